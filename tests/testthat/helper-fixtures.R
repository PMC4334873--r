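# shared fixture builders and independent oracles

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# random small assembly over the full scoring alphabet
random_assembly <- function(n_contigs = 3, min_len = 50, max_len = 400,
                            name = "rand") {
  seqs <- vapply(seq_len(n_contigs), function(i) {
    len <- sample(min_len:max_len, 1)
    paste(sample(c("A", "C", "G", "T", "N", "R", "Y"), len, replace = TRUE,
                 prob = c(0.22, 0.22, 0.22, 0.22, 0.06, 0.03, 0.03)),
          collapse = "")
  }, character(1))
  names(seqs) <- paste0("c", seq_len(n_contigs))
  genome_assembly(name, seqs)
}

# character-by-character recomputation of the sequence quality score,
# independent of compute_assembly_metrics / sequence_quality_score
brute_sequence_quality <- function(assembly, status, config = scoring_config()) {
  good <- 0; bad <- 0; gaps <- 0
  for (s in assembly$sequences) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    run <- 0
    for (c in c(ch, "$")) {
      if (c == "N") {
        run <- run + 1
      } else {
        if (run >= config$gap_min_run) gaps <- gaps + 1
        run <- 0
      }
    }
    good <- good + sum(ch %in% c("A", "C", "G", "T"))
    bad <- bad + sum(!ch %in% c("A", "C", "G", "T", "N"))
  }
  contig_pen <- if (status == "draft") {
    config$contig_penalty_bp * max(0, length(assembly$sequences) - 1)
  } else 0
  good / (good + bad + contig_pen + config$gap_penalty_bp * gaps)
}

# independent MD5 via base R's file-level implementation
md5_oracle <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(charToRaw(x), f)
  unname(tools::md5sum(f))
}

# feature set covering a chosen number of standard amino acids
trna_covering <- function(n_covered, pseudo_extra = 0) {
  rows <- data.frame(amino_acid = STANDARD_AMINO_ACIDS[seq_len(n_covered)],
                     anticodon = rep(NA_character_, n_covered),
                     pseudo = rep(FALSE, n_covered),
                     stringsAsFactors = FALSE)
  if (pseudo_extra > 0) {
    rows <- rbind(rows, data.frame(
      amino_acid = STANDARD_AMINO_ACIDS[seq_len(pseudo_extra)],
      anticodon = NA_character_, pseudo = TRUE, stringsAsFactors = FALSE))
  }
  rows
}

domain_hits_present <- function(n_present, config = scoring_config()) {
  data.frame(domain_accession = config$essential_domains[seq_len(n_present)],
             gene_id = if (n_present > 0) paste0("g", seq_len(n_present)) else character(),
             stringsAsFactors = FALSE)
}

ideal_rrnas <- function() {
  data.frame(molecule = c("5S", "16S", "23S"),
             length = c(110, 1550, 3100), stringsAsFactors = FALSE)
}

random_feature_set <- function(name = "rand_fs") {
  n_tr <- sample(0:6, 1)
  trnas <- if (n_tr > 0) data.frame(
    amino_acid = sample(c(STANDARD_AMINO_ACIDS, "SeC", "other"), n_tr, replace = TRUE),
    anticodon = ifelse(runif(n_tr) < 0.2, NA_character_,
                       replicate(n_tr, paste(sample(c("A", "C", "G", "T"), 3,
                                                    replace = TRUE), collapse = ""))),
    pseudo = runif(n_tr) < 0.3, stringsAsFactors = FALSE) else NULL
  n_rr <- sample(0:4, 1)
  rrnas <- if (n_rr > 0) data.frame(
    molecule = sample(c("5S", "16S", "23S"), n_rr, replace = TRUE),
    length = sample(50:4000, n_rr), stringsAsFactors = FALSE) else NULL
  n_g <- sample(0:5, 1)
  genes <- if (n_g > 0) data.frame(
    id = paste0("g", seq_len(n_g)), length_nt = sample(90:3000, n_g),
    stringsAsFactors = FALSE) else NULL
  n_d <- sample(0:5, 1)
  domains <- if (n_d > 0) data.frame(
    domain_accession = sample(scoring_config()$essential_domains, n_d),
    gene_id = paste0("g", sample(10, n_d)), stringsAsFactors = FALSE) else NULL
  args <- list(genome_name = name)
  if (!is.null(trnas)) args$trnas <- trnas
  if (!is.null(rrnas)) args$rrnas <- rrnas
  if (!is.null(genes)) args$genes <- genes
  if (!is.null(domains)) args$domains <- domains
  do.call(feature_set, args)
}
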