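#' Sequence-quality component score
#'
#' The fraction of "good" bases (A/C/G/T) out of good bases plus bad bases
#' (IUPAC ambiguity codes) plus penalty bases: `contig_penalty_bp` (default
#' 10,000) for each contig after the first, and `gap_penalty_bp` (default
#' 10,000) for each run of N of at least `gap_min_run` bases. Complete
#' genomes are penalized for gaps but not for additional contigs, which are
#' assumed to be additional replicons. The contig/gap penalty approximates
#' the genes lost at contig edges, scaled up tenfold so that fragmented
#' assemblies score clearly below finished ones.
#'
#' @param metrics An [compute_assembly_metrics()] result.
#' @param status `"draft"` or `"complete"`.
#' @param config A [scoring_config()].
#' @return Score in \[0, 1\]. A degenerate assembly with no good bases
#'   scores 0 with a warning.
#' @examples
#' m <- list(good_bases = 2e6, bad_bases = 0, gap_count = 0, contig_count = 2)
#' class(m) <- "assembly_metrics"
#' sequence_quality_score(m, "draft")  # 2e6 / 2.01e6
#' @export
sequence_quality_score <- function(metrics, status = c("draft", "complete"),
                                   config = scoring_config()) {
  stopifnot(inherits(metrics, "assembly_metrics"))
  status <- match.arg(status)
  good <- metrics$good_bases
  if (good == 0) {
    warning("assembly has no good (A/C/G/T) bases; sequence quality score is 0")
    return(0)
  }
  contig_pen <- if (status == "draft") {
    config$contig_penalty_bp * max(0L, metrics$contig_count - 1L)
  } else 0
  denom <- good + metrics$bad_bases + contig_pen +
    config$gap_penalty_bp * metrics$gap_count
  good / denom
}

#' rRNA component score
#'
#' Starts from a base of 0.1 and, for each molecule type (5S, 16S, 23S),
#' adds the best tier attained by any prediction of that type: 0.3 if some
#' prediction's length falls within the ideal window, else 0.2 if some
#' prediction is longer than half the window minimum, else 0.1 if any
#' prediction exists. With no predictions at all the score is the 0.1 base.
#' One full-length copy demonstrates completeness, so multi-copy operons
#' neither help nor hurt beyond their best copy.
#'
#' Predictions longer than the ideal maximum still earn the 0.2 tier (the
#' tier rules are applied literally); such over-long predictions are
#' reported in an `"overlong"` attribute so callers can flag them, because
#' they usually indicate embedded Ns, atypical genomic regions or predictor
#' weakness rather than an intact gene.
#'
#' @param rrnas Data frame of rRNA predictions (see [feature_set()]); may
#'   be empty.
#' @param config A [scoring_config()].
#' @return Score in \[0.1, 1\] in steps of 0.1, with attribute `overlong`
#'   naming molecule types having predictions above their ideal maximum.
#' @examples
#' rrna_score(data.frame(molecule = c("5S", "16S", "23S"),
#'                       length = c(110, 1550, 3000)))  # 1.0
#' rrna_score(empty_rrnas())                             # 0.1
#' @export
rrna_score <- function(rrnas, config = scoring_config()) {
  rrnas <- coerce_cols(rrnas, empty_rrnas(), "rrnas")
  inc <- config$rrna_tier_increments
  score <- config$rrna_base
  overlong <- character()
  for (i in seq_len(nrow(config$rrna_ranges))) {
    mol <- config$rrna_ranges$molecule[i]
    lo <- config$rrna_ranges$min_ideal[i]
    hi <- config$rrna_ranges$max_ideal[i]
    lens <- rrnas$length[rrnas$molecule == mol]
    if (length(lens) == 0L) next
    tier <- if (any(lens >= lo & lens <= hi)) inc[1]
            else if (any(lens > 0.5 * lo)) inc[2]
            else inc[3]
    score <- score + tier
    if (any(lens > hi)) overlong <- c(overlong, mol)
  }
  structure(score, overlong = overlong)
}

#' tRNA component score
#'
#' Starts from 1.0 and subtracts 0.1 for each of the 20 standard amino acids
#' with no non-pseudo tRNA, floored at 0.1 (reached at 9 or more missing).
#' Pseudo-tRNA predictions never demonstrate coverage, and non-standard
#' types (selenocysteine, undetermined) do not count toward the 20. Coverage
#' is decided by the predictor's amino-acid call, not by translating the
#' anticodon.
#'
#' @param trnas Data frame of tRNA predictions (see [feature_set()]); may be
#'   empty.
#' @param config A [scoring_config()].
#' @return Score in \{0.1, 0.2, ..., 1.0\}.
#' @examples
#' trna_score(data.frame(amino_acid = STANDARD_AMINO_ACIDS,
#'                       anticodon = NA, pseudo = FALSE))  # 1.0
#' trna_score(empty_trnas())                                # 0.1
#' @export
trna_score <- function(trnas, config = scoring_config()) {
  trnas <- coerce_cols(trnas, empty_trnas(), "trnas")
  covered <- unique(trnas$amino_acid[!trnas$pseudo])
  missing <- sum(!STANDARD_AMINO_ACIDS %in% covered)
  max(config$trna_floor, 1 - config$trna_decrement * missing)
}

#' Essential-gene component score
#'
#' Starts from 1.0 and subtracts 0.01 for each domain of the configured
#' essential panel (default: 102 universal Pfam-A domains) with no hit,
#' floored at 0.1. Presence is per distinct accession (version-stripped);
#' copies do not add.
#'
#' @param domains Data frame of domain hits (see [feature_set()]); may be
#'   empty.
#' @param config A [scoring_config()].
#' @return Score in \[0.1, 1\].
#' @examples
#' cfg <- scoring_config()
#' hits <- data.frame(domain_accession = cfg$essential_domains[1:92],
#'                    gene_id = paste0("g", 1:92))
#' essential_gene_score(hits, cfg)  # 0.90
#' @export
essential_gene_score <- function(domains, config = scoring_config()) {
  domains <- coerce_cols(domains, empty_domains(), "domains")
  present <- unique(strip_accession_version(domains$domain_accession))
  missing <- sum(!config$essential_domains %in% present)
  max(config$essential_floor, 1 - config$essential_decrement * missing)
}

#' Raw combined score
#'
#' The arithmetic mean of the four component scores. This is the score to
#' use for a single genome, where cohort standardization has nothing to
#' standardize against.
#'
#' @param components A `component_scores` object, or a numeric vector/list
#'   with elements `sequence_quality`, `rrna`, `trna`, `essential`.
#' @return Score in \[0, 1\].
#' @export
raw_combined <- function(components) {
  x <- unlist(components[c("sequence_quality", "rrna", "trna", "essential")])
  if (length(x) != 4L || anyNA(x)) stop("need the four component scores")
  mean(x)
}

#' Score one genome: the four components plus their raw mean
#'
#' Stage 1 measures the metrics and feature presence; stage 2 applies the
#' scoring scales. This function runs both stages for one genome.
#'
#' @param assembly A [genome_assembly()] (its `status` decides the contig
#'   penalty exemption).
#' @param features A [feature_set()] for the same genome.
#' @param config A [scoring_config()].
#' @return An object of class `component_scores`: list with
#'   `sequence_quality`, `rrna`, `trna`, `essential`, `raw_combined`, plus
#'   `genome` and `flags` (e.g. over-long rRNA warnings).
#' @export
score_genome <- function(assembly, features, config = scoring_config()) {
  stopifnot(inherits(assembly, "genome_assembly"), inherits(features, "feature_set"))
  metrics <- compute_assembly_metrics(assembly, config)
  sq <- sequence_quality_score(metrics, assembly$status, config)
  rr <- rrna_score(features$rrnas, config)
  flags <- character()
  if (length(attr(rr, "overlong")) > 0L) {
    flags <- paste0("overlong-rRNA:", paste(attr(rr, "overlong"), collapse = "/"))
  }
  comp <- list(
    genome = assembly$name,
    sequence_quality = as.numeric(sq),
    rrna = as.numeric(rr),
    trna = trna_score(features$trnas, config),
    essential = essential_gene_score(features$domains, config),
    flags = flags
  )
  comp$raw_combined <- raw_combined(comp)
  structure(comp, class = "component_scores")
}

#' @export
print.component_scores <- function(x, ...) {
  cat(sprintf("<component_scores> %s\n", x$genome))
  cat(sprintf("  sequence quality: %.2f\n  rRNA:             %.2f\n",
              x$sequence_quality, x$rrna))
  cat(sprintf("  tRNA:             %.2f\n  essential genes:  %.2f\n",
              x$trna, x$essential))
  cat(sprintf("  raw combined:     %.2f\n", x$raw_combined))
  if (length(x$flags) > 0L) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

# one-row data frame view of a component_scores object
#' @export
as.data.frame.component_scores <- function(x, ...) {
  data.frame(genome = x$genome,
             sequence_quality = x$sequence_quality,
             rrna = x$rrna, trna = x$trna, essential = x$essential,
             raw_combined = x$raw_combined,
             flags = paste(x$flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Write per-genome score cards
#'
#' One row per genome with the four components, the raw combined score, the
#' standardized total when available, and provenance columns. Scores are
#' displayed rounded to 2 decimals; internal computation is never rounded.
#'
#' @param scores Data frame of scores (e.g. from [score_cohort()]'s
#'   `$scores`, or rbind-ed [score_genome()] rows).
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return Invisibly, the displayed data frame.
#' @export
write_score_cards <- function(scores, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  scores <- as.data.frame(scores)
  num <- vapply(scores, is.numeric, logical(1))
  disp <- scores
  disp[num] <- lapply(disp[num], function(v) round(v, 2))
  if (format == "tsv") {
    utils::write.table(disp, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  } else {
    jsonlite::write_json(disp, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  }
  invisible(disp)
}
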