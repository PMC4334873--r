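#' Construct a per-genome feature set
#'
#' Canonical container for the four feature classes the scorers consume:
#' tRNA predictions, rRNA predictions, protein-coding genes and essential
#' domain hits. Any list may be empty.
#'
#' @param genome_name Non-empty string.
#' @param trnas Data frame with columns `amino_acid` (three-letter code, or
#'   `"SeC"`/`"other"` for non-standard types), `anticodon` (3-mer over
#'   A/C/G/T in the DNA alphabet, or `NA` when unknown) and `pseudo`
#'   (logical).
#' @param rrnas Data frame with columns `molecule` (`"5S"`, `"16S"` or
#'   `"23S"`) and `length` (bp, >= 1).
#' @param genes Data frame with columns `id` and `length_nt` (bp, >= 3).
#' @param domains Data frame with columns `domain_accession` and `gene_id`.
#' @return An object of class `feature_set`.
#' @export
feature_set <- function(genome_name,
                        trnas = empty_trnas(),
                        rrnas = empty_rrnas(),
                        genes = empty_genes(),
                        domains = empty_domains()) {
  if (!is.character(genome_name) || length(genome_name) != 1L || !nzchar(genome_name)) {
    stop("genome_name must be a non-empty string")
  }
  trnas <- coerce_cols(trnas, empty_trnas(), "trnas")
  rrnas <- coerce_cols(rrnas, empty_rrnas(), "rrnas")
  genes <- coerce_cols(genes, empty_genes(), "genes")
  domains <- coerce_cols(domains, empty_domains(), "domains")
  known <- !is.na(trnas$anticodon)
  if (any(known & nchar(trnas$anticodon) != 3L)) {
    stop("known anticodons must be 3 letters")
  }
  if (any(!nzchar(trnas$amino_acid))) stop("amino_acid must always be set")
  if (nrow(rrnas) > 0L) {
    if (!all(rrnas$molecule %in% c("5S", "16S", "23S"))) {
      stop("rRNA molecule must be one of 5S, 16S, 23S")
    }
    if (any(rrnas$length < 1)) stop("rRNA length must be >= 1")
  }
  if (nrow(genes) > 0L && any(genes$length_nt < 3)) stop("gene length_nt must be >= 3")
  if (nrow(domains) > 0L && any(!nzchar(domains$domain_accession))) {
    stop("domain_accession must be non-empty")
  }
  structure(
    list(genome_name = genome_name, trnas = trnas, rrnas = rrnas,
         genes = genes, domains = domains),
    class = "feature_set"
  )
}

empty_trnas <- function() {
  data.frame(amino_acid = character(), anticodon = character(),
             pseudo = logical(), stringsAsFactors = FALSE)
}
empty_rrnas <- function() {
  data.frame(molecule = character(), length = numeric(), stringsAsFactors = FALSE)
}
empty_genes <- function() {
  data.frame(id = character(), length_nt = numeric(), stringsAsFactors = FALSE)
}
empty_domains <- function() {
  data.frame(domain_accession = character(), gene_id = character(),
             stringsAsFactors = FALSE)
}

# coerce a user-supplied data frame onto a template's column set and modes
coerce_cols <- function(x, template, what) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  missing_cols <- setdiff(names(template), names(x))
  if (length(missing_cols) > 0L) {
    stop(what, " is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  x <- x[names(template)]
  for (col in names(template)) {
    x[[col]] <- if (is.logical(template[[col]])) as.logical(x[[col]])
                else if (is.numeric(template[[col]])) as.numeric(x[[col]])
                else as.character(x[[col]])
  }
  rownames(x) <- NULL
  x
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %s: %d tRNA (%d pseudo), %d rRNA, %d genes, %d domain hits\n",
              x$genome_name, nrow(x$trnas), sum(x$trnas$pseudo), nrow(x$rrnas),
              nrow(x$genes), nrow(x$domains)))
  invisible(x)
}

#' Parse tRNAscan-SE tabular output
#'
#' Reads the classic tabular format (3-line header, then whitespace-delimited
#' rows with sequence name, tRNA number, begin, end, type, anticodon, intron
#' bounds and score). Rows typed `Pseudo`, or whose trailing note column
#' flags a pseudogene, are marked `pseudo = TRUE`. `SeC`/`Sec` is kept as the
#' non-standard type `"SeC"`; `Undet`/`Sup` become `"other"` — an
#' undetermined isotype cannot demonstrate coverage of any standard amino
#' acid. Unknown anticodons (`???`/`NNN`) become `NA`.
#'
#' @param path Path to a tRNAscan-SE output file.
#' @return Data frame of tRNA genes (see [feature_set()]).
#' @export
parse_trnascan <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) <= 3L) return(empty_trnas())
  body <- lines[-(1:3)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) return(empty_trnas())
  out <- lapply(seq_along(body), function(i) {
    f <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(f) < 9L) {
      stop("malformed tRNAscan-SE row at line ", i + 3L, ": ", body[i])
    }
    type <- f[5]
    anticodon <- toupper(f[6])
    pseudo <- identical(type, "Pseudo") ||
      any(grepl("pseudo", f[-(1:9)], ignore.case = TRUE))
    aa <- if (identical(type, "Pseudo")) "other"
          else if (type %in% c("SeC", "Sec", "SeC(p)")) "SeC"
          else if (type %in% c("Undet", "Sup", "iMet?")) "other"
          else type
    if (!grepl("^[ACGT]{3}$", anticodon)) anticodon <- NA_character_
    data.frame(amino_acid = aa, anticodon = anticodon, pseudo = pseudo,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Parse RNAmmer GFF2 output
#'
#' RNAmmer writes GFF2-style lines whose attribute column is a bare molecule
#' name (`5s_rRNA`, `16s_rRNA`, `23s_rRNA`). Lengths are derived from the
#' 1-based inclusive coordinates (`end - start + 1`), never read from
#' attributes. Lines naming an unknown molecule are skipped with a warning.
#'
#' @param path Path to an RNAmmer GFF file.
#' @return Data frame of rRNA genes (see [feature_set()]).
#' @export
parse_rnammer_gff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gff <- tryCatch(ape::read.gff(path, GFF3 = FALSE),
                  error = function(e) NULL)
  if (is.null(gff) || nrow(gff) == 0L) return(empty_rrnas())
  mol <- toupper(sub("_RRNA$", "", toupper(trimws(gff$attributes))))
  keep <- mol %in% c("5S", "16S", "23S")
  if (any(!keep)) {
    warning("skipping rRNA line(s) with unknown molecule: ",
            paste(unique(gff$attributes[!keep]), collapse = ", "))
  }
  gff <- gff[keep, , drop = FALSE]
  mol <- mol[keep]
  if (nrow(gff) == 0L) return(empty_rrnas())
  if (any(gff$end < gff$start)) stop("rRNA feature with end < start")
  data.frame(molecule = mol, length = gff$end - gff$start + 1,
             stringsAsFactors = FALSE)
}

#' Parse Prodigal GFF3 gene predictions
#'
#' One protein gene per CDS feature; `length_nt = end - start + 1` (1-based
#' inclusive). Genes without an `ID` attribute get a synthesized id
#' `<contig>_<ordinal>`.
#'
#' @param path Path to a Prodigal GFF3 file.
#' @return Data frame of protein genes (see [feature_set()]).
#' @export
parse_prodigal_genes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gff <- tryCatch(ape::read.gff(path), error = function(e) NULL)
  if (is.null(gff) || nrow(gff) == 0L) return(empty_genes())
  gff <- gff[gff$type == "CDS", , drop = FALSE]
  if (nrow(gff) == 0L) return(empty_genes())
  ids <- sub("^.*?ID=([^;]+).*$", "\\1", gff$attributes)
  no_id <- !grepl("ID=", gff$attributes, fixed = TRUE)
  if (any(no_id)) {
    ord <- stats::ave(seq_len(nrow(gff)), gff$seqid, FUN = seq_along)
    ids[no_id] <- paste0(gff$seqid[no_id], "_", ord[no_id])
  }
  data.frame(id = ids, length_nt = gff$end - gff$start + 1,
             stringsAsFactors = FALSE)
}

#' Parse HMMER3 per-domain tabular output
#'
#' Reads `--domtblout` format and keeps rows whose Pfam accession
#' (version-stripped) is in `essential_domains`. Works with either search
#' direction: the accession is taken from whichever of the target/query
#' accession columns looks like a Pfam accession, and the gene id from the
#' opposite name column. Duplicate hits for one domain are all returned;
#' presence, not count, matters downstream.
#'
#' @param path Path to a domtblout file.
#' @param essential_domains Character vector of accessions to retain
#'   (version-stripped or not).
#' @param max_evalue Optional full-sequence E-value cutoff; `Inf` (default)
#'   applies no threshold, deferring filtering to whoever produced the file.
#' @return Data frame of domain hits (see [feature_set()]).
#' @export
parse_hmmer_domtbl <- function(path, essential_domains = default_essential_domains(),
                               max_evalue = Inf) {
  if (!file.exists(path)) stop("file not found: ", path)
  essential_domains <- strip_accession_version(essential_domains)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  body <- lines[keep]
  lineno <- which(keep)
  if (length(body) == 0L) return(empty_domains())
  out <- lapply(seq_along(body), function(i) {
    f <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(f) < 13L) {
      stop("malformed domtblout row at line ", lineno[i], ": ", body[i])
    }
    # domtblout: target name(1) acc(2) tlen(3) query name(4) acc(5) qlen(6) E-value(7)
    t_acc <- strip_accession_version(f[2])
    q_acc <- strip_accession_version(f[5])
    if (grepl("^PF\\d{5}$", t_acc)) {
      acc <- t_acc; gene <- f[4]
    } else if (grepl("^PF\\d{5}$", q_acc)) {
      acc <- q_acc; gene <- f[1]
    } else {
      acc <- q_acc; gene <- f[1]
    }
    data.frame(domain_accession = acc, gene_id = gene,
               evalue = suppressWarnings(as.numeric(f[7])),
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, out)
  hits <- hits[!is.na(hits$evalue) & hits$evalue <= max_evalue |
                 is.na(hits$evalue) & is.infinite(max_evalue), , drop = FALSE]
  hits <- hits[hits$domain_accession %in% essential_domains,
               c("domain_accession", "gene_id"), drop = FALSE]
  rownames(hits) <- NULL
  hits
}
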