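#' Scoring configuration
#'
#' Bundles every numeric constant of the quality-scoring scheme so that all
#' scorers and filters draw on a single, inspectable object. Defaults follow
#' the published scheme: a 10,000 bp penalty per extra contig and per N-gap,
#' N runs of 10 or more bases counted as gaps, size filters at 138,500 bp
#' (below: plasmid) and 18,000,000 bp (above: eukaryote), rRNA ideal length
#' windows of 2900-3500 (23S), 1450-1700 (16S) and 100-120 (5S), a 0.1 tRNA
#' decrement per uncovered standard amino acid and a 0.01 decrement per
#' missing essential domain, both floored at 0.1.
#'
#' @param contig_penalty_bp Penalty, in bases added to the denominator, for
#'   each contig after the first in a draft assembly.
#' @param gap_penalty_bp Penalty, in bases, for each counted N-gap.
#' @param gap_min_run Minimum run length of consecutive N for a run to count
#'   as a gap.
#' @param min_retained_size Assemblies strictly smaller than this (bp) are
#'   classified as plasmids and filtered.
#' @param max_retained_size Assemblies strictly larger than this (bp) are
#'   classified as eukaryotic and filtered.
#' @param rrna_ranges Data frame with columns `molecule`, `min_ideal`,
#'   `max_ideal` giving the ideal length window per rRNA molecule type.
#' @param rrna_base Base rRNA score before any molecule-type tier is added.
#' @param rrna_tier_increments Numeric vector of the three tier increments:
#'   length within the ideal window; length above half the window minimum;
#'   any prediction at all.
#' @param trna_decrement Score subtracted per standard amino acid with no
#'   non-pseudo tRNA.
#' @param trna_floor Minimum attainable tRNA score.
#' @param essential_decrement Score subtracted per missing essential domain.
#' @param essential_floor Minimum attainable essential-gene score.
#' @param essential_domains Character vector of Pfam-A accessions
#'   (version-stripped) defining the essential-domain panel. Defaults to the
#'   packaged 102-entry panel (see [default_essential_domains()]).
#' @return An object of class `scoring_config`.
#' @examples
#' cfg <- scoring_config()
#' cfg$gap_min_run
#' @export
scoring_config <- function(contig_penalty_bp = 10000,
                           gap_penalty_bp = 10000,
                           gap_min_run = 10,
                           min_retained_size = 138500,
                           max_retained_size = 18000000,
                           rrna_ranges = default_rrna_ranges(),
                           rrna_base = 0.1,
                           rrna_tier_increments = c(ideal = 0.3, partial = 0.2, fragment = 0.1),
                           trna_decrement = 0.1,
                           trna_floor = 0.1,
                           essential_decrement = 0.01,
                           essential_floor = 0.1,
                           essential_domains = default_essential_domains()) {
  stopifnot(
    is.numeric(contig_penalty_bp), length(contig_penalty_bp) == 1L, contig_penalty_bp > 0,
    is.numeric(gap_penalty_bp), length(gap_penalty_bp) == 1L, gap_penalty_bp > 0,
    is.numeric(gap_min_run), length(gap_min_run) == 1L, gap_min_run >= 1,
    is.numeric(min_retained_size), min_retained_size > 0,
    is.numeric(max_retained_size), max_retained_size > min_retained_size,
    is.numeric(rrna_base), rrna_base > 0, rrna_base < 1,
    is.numeric(rrna_tier_increments), length(rrna_tier_increments) == 3L,
    all(diff(rrna_tier_increments) < 0),
    trna_decrement > 0, trna_floor > 0, trna_floor < 1,
    essential_decrement > 0, essential_floor > 0, essential_floor < 1
  )
  rrna_ranges <- as.data.frame(rrna_ranges)
  if (!all(c("molecule", "min_ideal", "max_ideal") %in% names(rrna_ranges))) {
    stop("rrna_ranges must have columns molecule, min_ideal, max_ideal")
  }
  if (any(rrna_ranges$min_ideal >= rrna_ranges$max_ideal)) {
    stop("each rRNA ideal range must satisfy min_ideal < max_ideal")
  }
  essential_domains <- strip_accession_version(as.character(essential_domains))
  if (length(essential_domains) == 0L) stop("essential_domains must be non-empty")
  if (anyDuplicated(essential_domains)) {
    stop("essential_domains contains duplicate accessions: ",
         paste(unique(essential_domains[duplicated(essential_domains)]), collapse = ", "))
  }
  structure(
    list(
      contig_penalty_bp = contig_penalty_bp,
      gap_penalty_bp = gap_penalty_bp,
      gap_min_run = as.integer(gap_min_run),
      min_retained_size = min_retained_size,
      max_retained_size = max_retained_size,
      rrna_ranges = rrna_ranges,
      rrna_base = rrna_base,
      rrna_tier_increments = unname(rrna_tier_increments),
      trna_decrement = trna_decrement,
      trna_floor = trna_floor,
      essential_decrement = essential_decrement,
      essential_floor = essential_floor,
      essential_domains = essential_domains
    ),
    class = "scoring_config"
  )
}

#' Default rRNA ideal length windows
#'
#' Full-length windows (bp) per molecule type: 5S 100-120, 16S 1450-1700,
#' 23S 2900-3500 (the 23S window is broad to accommodate intron-bearing
#' molecules).
#'
#' @return Data frame with columns `molecule`, `min_ideal`, `max_ideal`.
#' @export
default_rrna_ranges <- function() {
  data.frame(
    molecule = c("5S", "16S", "23S"),
    min_ideal = c(100, 1450, 2900),
    max_ideal = c(120, 1700, 3500),
    stringsAsFactors = FALSE
  )
}

#' Default essential-domain panel
#'
#' Reads the packaged panel of 102 universal prokaryotic Pfam-A domain
#' accessions (ribosomal proteins, translation factors, aminoacyl-tRNA
#' synthetases, RNA polymerase subunits and other core machinery). The
#' packaged file is a synthetic reconstruction of a universal single-copy
#' panel; any accession list can be substituted via
#' `scoring_config(essential_domains = ...)`.
#'
#' @param path Path to a panel file: comment lines start with `#`, first
#'   tab-separated field is the accession. Defaults to the packaged file.
#' @return Character vector of version-stripped accessions.
#' @export
default_essential_domains <- function(path = system.file("extdata", "essential_domains_synthetic.tsv",
                                                         package = "genomeqc")) {
  if (!nzchar(path) || !file.exists(path)) stop("essential-domain panel file not found")
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  acc <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
  strip_accession_version(acc)
}

#' Strip version suffixes from domain accessions
#'
#' `PF00312.14` and `PF00312` denote the same Pfam family; comparisons are
#' always made on the version-stripped accession. Idempotent.
#'
#' @param x Character vector of accessions.
#' @return Character vector with any trailing `.<digits>` removed.
#' @export
strip_accession_version <- function(x) {
  sub("\\.\\d+$", "", as.character(x))
}

#' @export
print.scoring_config <- function(x, ...) {
  cat("Genome quality scoring configuration\n")
  cat(sprintf("  contig penalty: %s bp; gap penalty: %s bp (N runs >= %d)\n",
              format(x$contig_penalty_bp, big.mark = ","),
              format(x$gap_penalty_bp, big.mark = ","), x$gap_min_run))
  cat(sprintf("  retained size window: [%s, %s] bp\n",
              format(x$min_retained_size, big.mark = ","),
              format(x$max_retained_size, big.mark = ",")))
  for (i in seq_len(nrow(x$rrna_ranges))) {
    cat(sprintf("  %s ideal length: %d-%d\n", x$rrna_ranges$molecule[i],
                x$rrna_ranges$min_ideal[i], x$rrna_ranges$max_ideal[i]))
  }
  cat(sprintf("  tRNA: -%.2g per missing amino acid, floor %.2g\n",
              x$trna_decrement, x$trna_floor))
  cat(sprintf("  essential genes: -%.2g per missing domain, floor %.2g (%d domains)\n",
              x$essential_decrement, x$essential_floor, length(x$essential_domains)))
  invisible(x)
}

#' The 20 standard amino acids
#'
#' Three-letter codes, as emitted by tRNAscan-SE; the tRNA score counts
#' coverage over exactly this set.
#' @export
STANDARD_AMINO_ACIDS <- c(
  "Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His", "Ile",
  "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp", "Tyr", "Val"
)
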