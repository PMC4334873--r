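#' Construct a genome assembly
#'
#' An assembly is an ordered set of contig (or replicon/scaffold) sequences
#' plus a sequencing status and free-form metadata. Sequences are
#' uppercase-normalized on construction, so soft-masked (lowercase) bases are
#' treated as ordinary sequence; masking is annotation, not sequence quality.
#'
#' @param name Assembly name (non-empty string).
#' @param sequences Named character vector, one element per contig; names are
#'   contig ids (non-empty, unique), values are sequences over the IUPAC
#'   nucleotide alphabet.
#' @param status `"draft"` or `"complete"`. A complete genome is one whose
#'   every replicon is a single contiguous sequence; its contig count is not
#'   penalized in the sequence-quality score.
#' @param metadata Named list of free-form metadata (source, genus,
#'   technology, coverage, ...).
#' @return An object of class `genome_assembly`.
#' @examples
#' genome_assembly("toy", c(chr = "ACGTACGT"), status = "complete")
#' @export
genome_assembly <- function(name, sequences, status = c("draft", "complete"),
                            metadata = list()) {
  status <- match.arg(status)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("assembly name must be a non-empty string")
  }
  if (length(sequences) == 0L) stop("no contigs")
  ids <- names(sequences)
  if (is.null(ids) || any(!nzchar(ids))) stop("every contig needs a non-empty id")
  if (anyDuplicated(ids)) {
    stop("duplicate contig id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  sequences <- toupper(as.character(sequences))
  names(sequences) <- ids
  if (any(!nzchar(sequences))) stop("contig sequences must have length >= 1")
  bad <- setdiff(unique(unlist(strsplit(sequences, "", fixed = TRUE), use.names = FALSE)),
                 IUPAC_NT)
  if (length(bad) > 0L) {
    stop("non-IUPAC nucleotide character(s): ", paste(sort(bad), collapse = " "))
  }
  structure(
    list(name = name, sequences = sequences, status = status, metadata = metadata),
    class = "genome_assembly"
  )
}

IUPAC_NT <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V", "N")

#' Read a genome assembly from a multi-FASTA file
#'
#' One contig per FASTA record, record order preserved, sequences uppercased.
#' Status and metadata come from the caller, never from the file.
#'
#' @param path Path to a FASTA file.
#' @param name Assembly name; defaults to the file name without extension.
#' @param status,metadata Passed to [genome_assembly()].
#' @return A `genome_assembly`.
#' @export
read_assembly_fasta <- function(path, name = sub("\\.(fa|fna|fasta)$", "", basename(path)),
                                status = c("draft", "complete"), metadata = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("no contigs in ", path)
  seqs <- as.character(recs)
  # record id = first whitespace-delimited token of the header
  ids <- vapply(strsplit(names(recs), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate contig id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(seqs) <- ids
  genome_assembly(name, seqs, status = status, metadata = metadata)
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat(sprintf("<genome_assembly> %s (%s): %d contig(s), %s bp\n",
              x$name, x$status, length(x$sequences),
              format(sum(nchar(x$sequences)), big.mark = ",")))
  invisible(x)
}

#' Compute base, contig and gap metrics for an assembly
#'
#' Counts the quantities the sequence-quality score consumes: good bases
#' (A/C/G/T), bad bases (anything except A/C/G/T/N, i.e. IUPAC ambiguity
#' codes), gaps (maximal runs of N of length at least `gap_min_run`, scanned
#' per contig — runs never span contig boundaries), and N bases outside
#' counted gap runs (which count toward total size only, neither good nor
#' bad).
#'
#' @param assembly A `genome_assembly`.
#' @param config A [scoring_config()].
#' @return An object of class `assembly_metrics`: a list with elements
#'   `good_bases`, `bad_bases`, `n_bases`, `gap_count`, `gap_bases`,
#'   `contig_count`, `total_size`.
#' @examples
#' a <- genome_assembly("toy", c(c1 = paste0(strrep("A", 20),
#'                                           strrep("N", 12), strrep("G", 20))))
#' compute_assembly_metrics(a)
#' @export
compute_assembly_metrics <- function(assembly, config = scoring_config()) {
  stopifnot(inherits(assembly, "genome_assembly"))
  seqs <- assembly$sequences
  good <- 0; bad <- 0; n_total <- 0; gap_count <- 0L; gap_bases <- 0
  for (s in seqs) {
    cnt <- tabulate(as.integer(charToRaw(s)), nbins = 256L)
    g <- sum(cnt[as.integer(charToRaw("ACGT"))])
    n <- cnt[as.integer(charToRaw("N"))]
    good <- good + g
    n_total <- n_total + n
    bad <- bad + nchar(s) - g - n
    if (n > 0) {
      runs <- gregexpr("N+", s, perl = TRUE)[[1]]
      lens <- attr(runs, "match.length")
      in_gap <- lens >= config$gap_min_run
      gap_count <- gap_count + sum(in_gap)
      gap_bases <- gap_bases + sum(lens[in_gap])
    }
  }
  structure(
    list(
      good_bases = good,
      bad_bases = bad,
      n_bases = n_total - gap_bases,
      gap_count = as.integer(gap_count),
      gap_bases = gap_bases,
      contig_count = length(seqs),
      total_size = sum(nchar(seqs))
    ),
    class = "assembly_metrics"
  )
}

#' @export
print.assembly_metrics <- function(x, ...) {
  cat(sprintf(paste0("<assembly_metrics> %s bp in %d contig(s): %s good, ",
                     "%s bad, %s loose N, %d gap(s) (%s N in gaps)\n"),
              format(x$total_size, big.mark = ","), x$contig_count,
              format(x$good_bases, big.mark = ","),
              format(x$bad_bases, big.mark = ","),
              format(x$n_bases, big.mark = ","),
              x$gap_count, format(x$gap_bases, big.mark = ",")))
  invisible(x)
}

#' Fingerprint an assembly for deduplication
#'
#' The fingerprint is an MD5 checksum of checksums: each contig's uppercase
#' sequence bytes are hashed with MD5, the per-contig hex digests are sorted
#' lexicographically and joined with commas (no spaces), and the fingerprint
#' is the MD5 hex digest of that joined string. Sorting makes the fingerprint
#' invariant under contig order; contig ids and descriptions are excluded
#' because names differ across repositories while the sequence does not.
#'
#' @param assembly A `genome_assembly`.
#' @return A 32-character lowercase hex string.
#' @export
genome_fingerprint <- function(assembly) {
  stopifnot(inherits(assembly, "genome_assembly"))
  if (length(assembly$sequences) == 0L) stop("empty assembly")
  per_contig <- vapply(assembly$sequences, function(s) {
    digest::digest(toupper(s), algo = "md5", serialize = FALSE)
  }, character(1), USE.NAMES = FALSE)
  digest::digest(paste(sort(per_contig), collapse = ","),
                 algo = "md5", serialize = FALSE)
}

#' Classify an assembly by total size
#'
#' Assemblies strictly below the lower threshold are taken to be stray
#' plasmids; assemblies strictly above the upper threshold are taken to be
#' eukaryotic. Boundary sizes are retained (the exclusions are strict
#' inequalities).
#'
#' @param x An `assembly_metrics`, a `genome_assembly`, or a numeric total
#'   size in bp.
#' @param config A [scoring_config()].
#' @return One of `"retained"`, `"plasmid_too_small"`, `"eukaryote_too_large"`.
#' @examples
#' classify_by_size(138499)  # plasmid_too_small
#' classify_by_size(138500)  # retained
#' @export
classify_by_size <- function(x, config = scoring_config()) {
  size <- if (inherits(x, "assembly_metrics")) {
    x$total_size
  } else if (inherits(x, "genome_assembly")) {
    sum(nchar(x$sequences))
  } else if (is.numeric(x)) {
    x
  } else {
    stop("x must be assembly_metrics, genome_assembly, or numeric")
  }
  ifelse(size < config$min_retained_size, "plasmid_too_small",
         ifelse(size > config$max_retained_size, "eukaryote_too_large", "retained"))
}

#' Deduplicate a cohort of assemblies by fingerprint
#'
#' Keeps the first assembly (input order) of every fingerprint group; later
#' assemblies with the same fingerprint are reported as duplicates.
#'
#' @param assemblies List of `genome_assembly` objects.
#' @return A list with elements `unique` (list of representatives, input
#'   order), `duplicates` (named list: fingerprint -> character vector of all
#'   assembly names sharing it; only groups of size >= 2), and `table` (data
#'   frame with columns `name`, `fingerprint`, `total_size`, `size_class`,
#'   `duplicate_of` — `NA` for representatives).
#' @export
dedupe_cohort <- function(assemblies, config = scoring_config()) {
  stopifnot(is.list(assemblies), length(assemblies) >= 1L)
  fps <- vapply(assemblies, genome_fingerprint, character(1))
  names_ <- vapply(assemblies, function(a) a$name, character(1))
  sizes <- vapply(assemblies, function(a) sum(nchar(a$sequences)), numeric(1))
  first <- !duplicated(fps)
  rep_name <- names_[first][match(fps, fps[first])]
  tab <- data.frame(
    name = names_,
    fingerprint = fps,
    total_size = sizes,
    size_class = classify_by_size(sizes, config),
    duplicate_of = ifelse(first, NA_character_, rep_name),
    stringsAsFactors = FALSE
  )
  groups <- split(names_, fps)
  groups <- groups[vapply(groups, length, integer(1)) >= 2L]
  list(unique = assemblies[first], duplicates = groups, table = tab)
}

#' Write a dedupe/size report
#'
#' @param assemblies List of `genome_assembly` objects.
#' @param path Output TSV path.
#' @param config A [scoring_config()].
#' @return Invisibly, the report data frame.
#' @export
write_dedupe_report <- function(assemblies, path, config = scoring_config()) {
  tab <- dedupe_cohort(assemblies, config)$table
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(tab)
}
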