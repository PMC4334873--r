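#' Write a feature set to the native feature-table format
#'
#' The native format lets the scorers run with no external predictors. It is
#' a plain-text, tab-separated, sectioned file:
#'
#' ```
#' #genomeqc-features 1
#' genome <TAB> <name>
#' [trna]
#' amino_acid <TAB> anticodon <TAB> pseudo
#' Met <TAB> CAT <TAB> FALSE
#' [rrna]
#' molecule <TAB> length
#' [gene]
#' id <TAB> length_nt
#' [domain]
#' domain_accession <TAB> gene_id
#' ```
#'
#' Sections may appear in any order; empty sections may be omitted. Unknown
#' anticodons are serialized as `.`.
#'
#' @param fs A [feature_set()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(fs, path) {
  stopifnot(inherits(fs, "feature_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#genomeqc-features 1", paste0("genome\t", fs$genome_name)), con)
  sect <- function(tag, df) {
    writeLines(paste0("[", tag, "]"), con)
    df_out <- df
    if ("anticodon" %in% names(df_out)) {
      df_out$anticodon[is.na(df_out$anticodon)] <- "."
    }
    utils::write.table(df_out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  sect("trna", fs$trnas)
  sect("rrna", fs$rrnas)
  sect("gene", fs$genes)
  sect("domain", fs$domains)
  invisible(path)
}

#' Read a feature set from the native feature-table format
#'
#' Inverse of [write_feature_table()]; `read_feature_table(write_feature_table(fs))`
#' reproduces `fs` exactly.
#'
#' @param path Path to a native feature-table file.
#' @return A [feature_set()].
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L || !startsWith(lines[1], "#genomeqc-features")) {
    stop("not a genomeqc feature table (missing #genomeqc-features header)")
  }
  lines <- lines[-1L]
  genome_line <- grep("^genome\t", lines)
  if (length(genome_line) != 1L) stop("feature table must have exactly one 'genome' line")
  genome_name <- sub("^genome\t", "", lines[genome_line])
  lines <- lines[-genome_line]
  sect_starts <- grep("^\\[[a-z]+\\]$", lines)
  if (length(sect_starts) == 0L) return(feature_set(genome_name))
  if (sect_starts[1] != 1L) {
    stop("unexpected content before first section: ", lines[1])
  }
  templates <- list(trna = empty_trnas(), rrna = empty_rrnas(),
                    gene = empty_genes(), domain = empty_domains())
  parts <- list()
  bounds <- c(sect_starts, length(lines) + 1L)
  for (k in seq_along(sect_starts)) {
    tag <- sub("^\\[([a-z]+)\\]$", "\\1", lines[sect_starts[k]])
    if (!tag %in% names(templates)) stop("unknown section: [", tag, "]")
    block <- lines[seq(sect_starts[k] + 1L, bounds[k + 1L] - 1L)]
    if (length(block) == 0L) { parts[[tag]] <- templates[[tag]]; next }
    header <- strsplit(block[1], "\t", fixed = TRUE)[[1]]
    unknown <- setdiff(header, names(templates[[tag]]))
    if (length(unknown) > 0L) {
      stop("unknown field(s) in [", tag, "]: ", paste(unknown, collapse = ", "))
    }
    if (length(block) == 1L) { parts[[tag]] <- templates[[tag]]; next }
    df <- utils::read.table(text = block[-1], sep = "\t", header = FALSE,
                            col.names = header, colClasses = "character",
                            stringsAsFactors = FALSE, quote = "")
    if ("anticodon" %in% names(df)) {
      df$anticodon[df$anticodon == "."] <- NA_character_
    }
    parts[[tag]] <- df
  }
  feature_set(genome_name,
              trnas = if (is.null(parts$trna)) empty_trnas() else parts$trna,
              rrnas = if (is.null(parts$rrna)) empty_rrnas() else parts$rrna,
              genes = if (is.null(parts$gene)) empty_genes() else parts$gene,
              domains = if (is.null(parts$domain)) empty_domains() else parts$domain)
}
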