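#' Standardize component scores across a cohort and combine
#'
#' For cohorts of two or more genomes, each component is standardized to
#' zero mean and unit variance (`z = (x - mu) / sigma`, population sigma; a
#' component with zero variance carries no ranking information and
#' contributes `z = 0` everywhere), the four z-scores are averaged per
#' genome, and the averages are min-max rescaled to \[0, 1\]. For a cohort
#' of one, or a cohort whose averaged z-scores are all identical, the
#' standardized total falls back to the raw combined score — with nothing to
#' rank, standardization is skipped, which is also the recommendation for
#' single-genome use.
#'
#' @param components A list of `component_scores` objects, or a data frame
#'   with columns `genome`, `sequence_quality`, `rrna`, `trna`, `essential`
#'   (a `raw_combined` column is recomputed if absent).
#' @return An object of class `genome_quality`: list with `scores` (data
#'   frame adding `standardized_total`), `stats` (per-component `mu` and
#'   `sigma`, and the rescale `min`/`max` of the averaged z-scores) and
#'   `combine_mode` (`"standardized"` or `"raw"`).
#' @examples
#' a <- data.frame(genome = c("g1", "g2"),
#'                 sequence_quality = c(1, 0.8), rrna = c(1, 0.3),
#'                 trna = c(1, 0.5), essential = c(1, 0.9))
#' standardize_and_combine(a)$scores$standardized_total  # 1 0
#' @export
standardize_and_combine <- function(components) {
  df <- components_frame(components)
  if (nrow(df) == 0L) stop("empty cohort")
  comp_cols <- c("sequence_quality", "rrna", "trna", "essential")
  mu <- vapply(df[comp_cols], mean, numeric(1))
  sigma <- vapply(df[comp_cols], pop_sd, numeric(1))
  if (nrow(df) == 1L) {
    df$standardized_total <- df$raw_combined
    return(new_genome_quality(df, mu, sigma, c(NA_real_, NA_real_), "raw"))
  }
  z <- mapply(function(x, m, s) if (s == 0) rep(0, length(x)) else (x - m) / s,
              df[comp_cols], mu, sigma)
  avg_z <- rowMeans(matrix(z, nrow = nrow(df)))
  lo <- min(avg_z); hi <- max(avg_z)
  if (hi - lo < .Machine$double.eps^0.5) {
    df$standardized_total <- df$raw_combined
    return(new_genome_quality(df, mu, sigma, c(lo, hi), "raw"))
  }
  df$standardized_total <- (avg_z - lo) / (hi - lo)
  new_genome_quality(df, mu, sigma, c(lo, hi), "standardized")
}

new_genome_quality <- function(scores, mu, sigma, rescale, mode) {
  structure(
    list(scores = scores,
         stats = list(mu = mu, sigma = sigma,
                      rescale = c(min = rescale[1], max = rescale[2])),
         combine_mode = mode),
    class = "genome_quality"
  )
}

# population (not sample) standard deviation: the cohort is the whole
# universe being scored, not a sample from one
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

components_frame <- function(components) {
  if (is.data.frame(components)) {
    df <- components
  } else if (is.list(components) &&
             all(vapply(components, inherits, logical(1), "component_scores"))) {
    df <- do.call(rbind, lapply(components, as.data.frame))
  } else {
    stop("components must be a data frame or a list of component_scores")
  }
  need <- c("genome", "sequence_quality", "rrna", "trna", "essential")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(df$raw_combined)) {
    df$raw_combined <- rowMeans(df[c("sequence_quality", "rrna", "trna", "essential")])
  }
  rownames(df) <- NULL
  df
}

#' Score a cohort of genomes
#'
#' The main entry point: scores every genome (four components plus raw
#' combined), then combines across the cohort. In `"auto"` mode the
#' standardized total is used for cohorts of two or more genomes and the raw
#' combined score for a single genome.
#'
#' @param assemblies List of [genome_assembly()] objects.
#' @param features List of [feature_set()] objects, matched to assemblies by
#'   name (or by position if names do not match).
#' @param config A [scoring_config()].
#' @param combine `"auto"`, `"raw"` or `"standardized"`.
#' @return A `genome_quality` object (see [standardize_and_combine()]); its
#'   `scores` element carries one row per genome.
#' @export
score_cohort <- function(assemblies, features, config = scoring_config(),
                         combine = c("auto", "raw", "standardized")) {
  combine <- match.arg(combine)
  stopifnot(is.list(assemblies), length(assemblies) >= 1L,
            is.list(features), length(features) == length(assemblies))
  fnames <- vapply(features, function(f) f$genome_name, character(1))
  anames <- vapply(assemblies, function(a) a$name, character(1))
  idx <- match(anames, fnames)
  if (anyNA(idx)) idx <- seq_along(assemblies)  # fall back to positional pairing
  comp <- lapply(seq_along(assemblies), function(i) {
    score_genome(assemblies[[i]], features[[idx[i]]], config)
  })
  gq <- standardize_and_combine(comp)
  if (combine == "raw" || (combine == "auto" && nrow(gq$scores) == 1L)) {
    gq$scores$standardized_total <- gq$scores$raw_combined
    gq$combine_mode <- "raw"
  }
  # carry genus/source metadata through for group-by analytics
  gq$metadata <- data.frame(
    genome = anames,
    genus = vapply(assemblies, function(a) meta_chr(a, "genus"), character(1)),
    source = vapply(assemblies, function(a) meta_chr(a, "source"), character(1)),
    status = vapply(assemblies, function(a) a$status, character(1)),
    stringsAsFactors = FALSE
  )
  gq
}

meta_chr <- function(a, key) {
  v <- a$metadata[[key]]
  if (is.null(v) || !nzchar(as.character(v))) NA_character_ else as.character(v)
}

#' @export
print.genome_quality <- function(x, ...) {
  cat(sprintf("<genome_quality> %d genome(s), combine mode: %s\n",
              nrow(x$scores), x$combine_mode))
  n <- min(nrow(x$scores), 10L)
  disp <- x$scores[seq_len(n), , drop = FALSE]
  num <- vapply(disp, is.numeric, logical(1))
  disp[num] <- lapply(disp[num], round, 2)
  print(disp, row.names = FALSE)
  if (nrow(x$scores) > n) cat("  ... and", nrow(x$scores) - n, "more\n")
  invisible(x)
}

#' @export
summary.genome_quality <- function(object, ...) {
  comp_cols <- c("sequence_quality", "rrna", "trna", "essential",
                 "raw_combined", "standardized_total")
  s <- t(vapply(object$scores[comp_cols], function(v) {
    c(mean = mean(v), sd = pop_sd(v), min = min(v), max = max(v))
  }, numeric(4)))
  res <- list(n = nrow(object$scores), combine_mode = object$combine_mode,
              component_summary = round(s, 4))
  class(res) <- "summary.genome_quality"
  res
}

#' @export
print.summary.genome_quality <- function(x, ...) {
  cat(sprintf("Genome quality summary: %d genome(s), combine mode %s\n",
              x$n, x$combine_mode))
  print(x$component_summary)
  invisible(x)
}

#' @export
as.data.frame.genome_quality <- function(x, ...) x$scores

#' Plot score distributions for a cohort
#'
#' One histogram panel per score column, mirroring the per-range score
#' distribution tables used to compare cohorts.
#'
#' @param x A `genome_quality` object.
#' @param breaks Bin edges over \[0, 1\].
#' @param ... Passed to [graphics::hist()].
#' @return Invisibly, `x`.
#' @export
plot.genome_quality <- function(x, breaks = (0:10) / 10, ...) {
  comp_cols <- c("sequence_quality", "rrna", "trna", "essential",
                 "raw_combined", "standardized_total")
  old <- graphics::par(mfrow = c(2, 3))
  on.exit(graphics::par(old))
  for (col in comp_cols) {
    graphics::hist(x$scores[[col]], breaks = breaks, main = col,
                   xlab = "score", col = "grey80", ...)
  }
  invisible(x)
}

# ---- anticodon analytics ----------------------------------------------------

#' The 62-anticodon alphabet
#'
#' All anticodons a genome's tRNAs can carry, in the DNA alphabet: the
#' reverse complements of the 61 sense codons plus TCA, the selenocysteine
#' anticodon (read against the recoded stop UGA).
#'
#' @return Character vector of 62 distinct 3-mers over A/C/G/T.
#' @export
anticodon_alphabet <- function() {
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  revcomp <- function(x) {
    chartr("ACGT", "TGCA", vapply(strsplit(x, ""), function(ch) {
      paste(rev(ch), collapse = "")
    }, character(1)))
  }
  sort(unique(c(revcomp(sense), "TCA")))
}

#' Default rare-anticodon set
#'
#' The anticodons beginning with A (pairing codons ending in U) are nearly
#' absent from predicted prokaryotic tRNA sets, with the sole exception of
#' ACG (arginine). The default rare set is therefore defined structurally:
#' the 16 A-starting anticodons minus ACG, 15 in all.
#'
#' @return Character vector of 15 anticodons.
#' @export
default_rare_anticodons <- function() {
  setdiff(grep("^A", anticodon_alphabet(), value = TRUE), "ACG")
}

#' Anticodon frequencies across a cohort
#'
#' Counts every anticodon carried by a non-pseudo tRNA across all feature
#' sets (optional types such as selenocysteine included). Unknown or
#' ambiguous anticodons are tallied under `"unknown"`, outside the
#' 62-member alphabet.
#'
#' @param feature_sets List of [feature_set()] objects (or one).
#' @param rare_set Anticodons flagged rare; default
#'   [default_rare_anticodons()].
#' @return An object of class `anticodon_table`: list with `counts` (named
#'   integer vector over the 62 anticodons, zeros kept), `unknown` (count)
#'   and `rare_set`.
#' @export
anticodon_frequency <- function(feature_sets, rare_set = default_rare_anticodons()) {
  if (inherits(feature_sets, "feature_set")) feature_sets <- list(feature_sets)
  alphabet <- anticodon_alphabet()
  counts <- stats::setNames(integer(length(alphabet)), alphabet)
  unknown <- 0L
  for (fs in feature_sets) {
    ac <- fs$trnas$anticodon[!fs$trnas$pseudo]
    known <- !is.na(ac) & ac %in% alphabet
    unknown <- unknown + sum(!known)
    t <- table(ac[known])
    counts[names(t)] <- counts[names(t)] + as.integer(t)
  }
  structure(list(counts = counts, unknown = unknown, rare_set = rare_set),
            class = "anticodon_table")
}

#' @export
print.anticodon_table <- function(x, ...) {
  cat(sprintf("<anticodon_table> %d observed tRNA anticodon(s) over a %d-member alphabet\n",
              sum(x$counts), length(x$counts)))
  rare_seen <- x$counts[names(x$counts) %in% x$rare_set]
  rare_seen <- rare_seen[rare_seen > 0]
  if (length(rare_seen) > 0L) {
    cat("  rare anticodons observed:",
        paste(sprintf("%s(%d)", names(rare_seen), rare_seen), collapse = ", "), "\n")
  } else {
    cat("  no rare anticodons observed\n")
  }
  if (x$unknown > 0L) cat("  unknown/ambiguous anticodons:", x$unknown, "\n")
  invisible(x)
}

#' Rare-anticodon incidence by group
#'
#' A genome counts once if it carries at least one non-pseudo tRNA whose
#' anticodon is in the rare set. Percentages are displayed with the same
#' convention as the published genus table (two significant digits, exact
#' halves toward zero, at most one decimal place); the unrounded percent is
#' also returned.
#'
#' @param feature_sets List of [feature_set()] objects.
#' @param groups Character vector of group labels (e.g. genus), one per
#'   feature set; empty or `NA` labels are grouped under `"unassigned"`.
#' @param rare_set Anticodons considered rare.
#' @return Data frame with columns `group`, `n_genomes`, `n_with_rare`,
#'   `percent` (exact) and `percent_display`.
#' @export
rare_anticodon_by_group <- function(feature_sets, groups,
                                    rare_set = default_rare_anticodons()) {
  stopifnot(length(groups) == length(feature_sets))
  groups <- as.character(groups)
  groups[is.na(groups) | !nzchar(groups)] <- "unassigned"
  has_rare <- vapply(feature_sets, function(fs) {
    ac <- fs$trnas$anticodon[!fs$trnas$pseudo]
    any(!is.na(ac) & ac %in% rare_set)
  }, logical(1))
  n <- tapply(has_rare, groups, length)
  k <- tapply(has_rare, groups, sum)
  pct <- 100 * as.numeric(k) / as.numeric(n)
  data.frame(group = names(n),
             n_genomes = as.integer(n),
             n_with_rare = as.integer(k),
             percent = pct,
             percent_display = percent_display(pct),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Display-round a percentage
#'
#' Two significant digits, exact halves rounded toward zero, then capped at
#' one decimal place: 87.5 displays as 87, 0.1378 as 0.1, 44.38 as 44.
#' Internal computation is never rounded; this affects display columns only.
#'
#' @param p Numeric vector of percentages.
#' @return Numeric vector of display values.
#' @export
percent_display <- function(p) {
  vapply(p, function(x) {
    if (!is.finite(x)) return(x)
    if (x == 0) return(0)
    sgn <- sign(x); x <- abs(x)
    e <- floor(log10(x)) - 1L          # scale for 2 significant digits
    s <- round_half_down(x / 10^e) * 10^e
    sgn * round_half_down(s * 10) / 10  # at most one decimal place
  }, numeric(1))
}

round_half_down <- function(x) ceiling(x - 0.5)

#' Gene length and density statistics
#'
#' @param genes Data frame of protein genes (see [feature_set()]).
#' @param total_size Assembly size in bp (> 0).
#' @return List with `mean_gene_length` (bp) and `gene_density` (genes per
#'   kb). An empty gene list yields both 0 with a warning.
#' @export
gene_stats <- function(genes, total_size) {
  stopifnot(is.numeric(total_size), total_size > 0)
  genes <- coerce_cols(genes, empty_genes(), "genes")
  if (nrow(genes) == 0L) {
    warning("no genes; gene statistics are 0")
    return(list(mean_gene_length = 0, gene_density = 0))
  }
  list(mean_gene_length = mean(genes$length_nt),
       gene_density = 1000 * nrow(genes) / total_size)
}

#' Score distribution per group
#'
#' For each group and each score column, the percentage of genomes falling
#' in each score bin. Bins are right-closed, so a bin is labelled by the
#' largest value in its range; percentages within a group/column sum to 100.
#'
#' @param scores A `genome_quality` object or its `scores` data frame.
#' @param groups Group labels, one per genome, or `NULL` for a single
#'   `"all"` group; empty/`NA` labels become `"unassigned"`.
#' @param breaks Strictly increasing bin edges covering \[0, 1\].
#' @param columns Score columns to tabulate.
#' @return Data frame with columns `group`, `score`, `bin_upper`, `percent`.
#' @export
score_distribution <- function(scores, groups = NULL, breaks = (0:10) / 10,
                               columns = c("sequence_quality", "rrna", "trna",
                                           "essential", "raw_combined",
                                           "standardized_total")) {
  if (inherits(scores, "genome_quality")) scores <- scores$scores
  stopifnot(all(diff(breaks) > 0), breaks[1] <= 0, breaks[length(breaks)] >= 1)
  columns <- intersect(columns, names(scores))
  if (is.null(groups)) groups <- rep("all", nrow(scores))
  groups <- as.character(groups)
  groups[is.na(groups) | !nzchar(groups)] <- "unassigned"
  stopifnot(length(groups) == nrow(scores))
  out <- list()
  for (g in unique(groups)) {
    sel <- groups == g
    for (col in columns) {
      bins <- cut(scores[[col]][sel], breaks = breaks, right = TRUE,
                  include.lowest = TRUE)
      pct <- 100 * as.numeric(table(bins)) / sum(sel)
      out[[length(out) + 1L]] <- data.frame(
        group = g, score = col, bin_upper = breaks[-1], percent = pct,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
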