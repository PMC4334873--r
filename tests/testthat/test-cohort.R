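two_genome_frame <- function() {
  data.frame(genome = c("better", "worse"),
             sequence_quality = c(1, 0.8), rrna = c(1, 0.4),
             trna = c(1, 0.6), essential = c(1, 0.9),
             stringsAsFactors = FALSE)
}

test_that("cohort standardization rescales to [0,1] and handles degenerate cohorts", {
  gq <- standardize_and_combine(two_genome_frame())
  expect_identical(gq$combine_mode, "standardized")
  expect_equal(gq$scores$standardized_total, c(1, 0))

  # single genome: fall back to the raw combined score
  one <- two_genome_frame()[1, ]
  gq1 <- standardize_and_combine(one)
  expect_equal(gq1$scores$standardized_total, gq1$scores$raw_combined)
  expect_identical(gq1$combine_mode, "raw")

  # identical genomes: zero-variance components carry no ranking information
  same <- two_genome_frame()[c(2, 2, 2), ]
  same$genome <- c("a", "b", "c")
  gqs <- standardize_and_combine(same)
  expect_equal(gqs$scores$standardized_total, gqs$scores$raw_combined)

  expect_error(standardize_and_combine(two_genome_frame()[0, ]), "empty")
})

test_that("standardization is affine-invariant per component and attains 0 and 1", {
  set.seed(55)
  for (i in 1:10) {
    n <- sample(3:12, 1)
    df <- data.frame(genome = paste0("g", 1:n),
                     sequence_quality = runif(n), rrna = runif(n),
                     trna = runif(n), essential = runif(n))
    gq <- standardize_and_combine(df)
    expect_equal(min(gq$scores$standardized_total), 0)
    expect_equal(max(gq$scores$standardized_total), 1)
    # shift and positively scale one component: z-scores are unchanged
    df2 <- df
    df2$rrna <- 0.3 + 2.5 * df2$rrna
    gq2 <- standardize_and_combine(df2)
    expect_equal(gq2$scores$standardized_total, gq$scores$standardized_total,
                 tolerance = 1e-9)
  }
})

test_that("standardized totals track raw scores on a simulated cohort", {
  coh <- simulate_cohort(
    50, simulation_params(genome_size = 40000), seed = 20,
    vary = function(i) list(missing_amino_acids = (i %% 5) * 2,
                            missing_domains = (i * 7) %% 40,
                            contig_count = 1 + (i %% 8) * 3,
                            gap_count = i %% 4,
                            rrna_profile = c("ideal", "half_min", "short",
                                             "absent", "overlong")[1 + i %% 5]))
  gq <- score_cohort(lapply(coh, `[[`, "assembly"),
                     lapply(coh, `[[`, "features"))
  rho <- cor(gq$scores$raw_combined, gq$scores$standardized_total,
             method = "spearman")
  expect_gte(rho, 0.9)
})

test_that("the anticodon alphabet has 62 members including the selenocysteine anticodon", {
  ab <- anticodon_alphabet()
  expect_length(ab, 62)
  expect_true(all(grepl("^[ACGT]{3}$", ab)))
  expect_false(anyDuplicated(ab) > 0)
  expect_true("TCA" %in% ab)          # SeC, read against recoded UGA
  expect_false("TTA" %in% ab)         # anticodon of stop UAA
  expect_false("CTA" %in% ab)         # anticodon of stop UAG
  # 16 A-starting anticodons; the rare set excludes only ACG
  a_start <- grep("^A", ab, value = TRUE)
  expect_length(a_start, 16)
  expect_setequal(default_rare_anticodons(), setdiff(a_start, "ACG"))
})

test_that("anticodon frequencies count non-pseudo tRNAs and flag rare ones", {
  fs1 <- feature_set("g1", trnas = data.frame(
    amino_acid = c("Met", "Met", "Cys", "Arg"),
    anticodon = c("CAT", "CAT", "ACA", "ACG"),
    pseudo = c(FALSE, FALSE, FALSE, TRUE)))
  fs2 <- feature_set("g2", trnas = data.frame(
    amino_acid = c("SeC", "Leu"), anticodon = c("TCA", NA), pseudo = FALSE))
  act <- anticodon_frequency(list(fs1, fs2))
  expect_identical(unname(act$counts["CAT"]), 2L)
  expect_identical(unname(act$counts["ACA"]), 1L)   # rare, observed
  expect_identical(unname(act$counts["ACG"]), 0L)   # pseudo excluded
  expect_identical(unname(act$counts["TCA"]), 1L)   # optional tRNAs counted
  expect_identical(act$unknown, 1L)                  # NA anticodon
  expect_identical(sum(act$counts), 4L)
  expect_true("ACA" %in% act$rare_set)
  expect_false("ACG" %in% act$rare_set)
})

test_that("rare-anticodon incidence reproduces the printed genus percentages", {
  # reconstruct groups with the published counts: a genome with a rare
  # anticodon carries ACA, one without carries only CAT
  with_rare <- feature_set("r", trnas = data.frame(
    amino_acid = "Cys", anticodon = "ACA", pseudo = FALSE))
  without <- feature_set("p", trnas = data.frame(
    amino_acid = "Met", anticodon = "CAT", pseudo = FALSE))
  build <- function(n, k, label) {
    list(sets = c(rep(list(with_rare), k), rep(list(without), n - k)),
         labels = rep(label, n))
  }
  b <- build(32, 28, "Butyrivibrio")
  e <- build(2177, 3, "Escherichia")
  l <- build(338, 150, "Lactobacillus")
  tab <- rare_anticodon_by_group(c(b$sets, e$sets, l$sets),
                                 c(b$labels, e$labels, l$labels))
  tab <- tab[match(c("Butyrivibrio", "Escherichia", "Lactobacillus"), tab$group), ]
  expect_identical(tab$n_with_rare, c(28L, 3L, 150L))
  expect_equal(tab$percent_display, c(87, 0.1, 44))

  # zero-rare group and unassigned labels
  z <- rare_anticodon_by_group(list(without, without), c("", NA))
  expect_identical(z$group, "unassigned")
  expect_equal(z$percent, 0)
})

test_that("gene statistics compute mean length and density per kilobase", {
  g4000 <- data.frame(id = paste0("g", 1:4000), length_nt = rep(900, 4000))
  st <- gene_stats(g4000, 4e6)
  expect_equal(st$mean_gene_length, 900)
  expect_equal(st$gene_density, 1.0)

  st1 <- gene_stats(data.frame(id = "g1", length_nt = 300), 1000)
  expect_equal(st1$mean_gene_length, 300)
  expect_equal(st1$gene_density, 1.0)

  expect_warning(st0 <- gene_stats(data.frame(id = character(),
                                              length_nt = numeric()), 1000))
  expect_equal(unlist(st0), c(mean_gene_length = 0, gene_density = 0))
})

test_that("score distributions are right-closed and normalize to 100 per group", {
  df <- data.frame(genome = paste0("g", 1:4),
                   sequence_quality = 1, rrna = 1, trna = 1, essential = 1)
  gq <- standardize_and_combine(df)
  d <- score_distribution(gq, columns = "raw_combined")
  expect_equal(d$percent[d$bin_upper == 1], 100)
  expect_equal(sum(d$percent), 100)

  # a score exactly on an interior edge falls in the lower bin (right-closed)
  edge <- data.frame(genome = c("a", "b"), sequence_quality = c(0.5, 0.51),
                     rrna = 0.1, trna = 0.1, essential = 0.1)
  de <- score_distribution(edge, columns = "sequence_quality")
  expect_equal(de$percent[de$bin_upper == 0.5], 50)
  expect_equal(de$percent[de$bin_upper == 0.6], 50)

  # near-uniform scores spread close to evenly over 10 bins
  set.seed(9)
  u <- data.frame(genome = paste0("g", 1:2000),
                  sequence_quality = runif(2000), rrna = 0.5, trna = 0.5,
                  essential = 0.5)
  du <- score_distribution(u, columns = "sequence_quality")
  expect_true(all(abs(du$percent - 10) < 3))
  expect_equal(sum(du$percent), 100, tolerance = 0.5)

  # per-group normalization with unassigned labels
  dg <- score_distribution(edge, groups = c("x", NA), columns = "sequence_quality")
  expect_setequal(unique(dg$group), c("x", "unassigned"))
  for (g in unique(dg$group)) {
    expect_equal(sum(dg$percent[dg$group == g]), 100)
  }
})

test_that("simulated group-wise quality differences separate in the scores", {
  coh <- simulate_cohort(
    20, simulation_params(genome_size = 30000), seed = 77,
    groups = list(
      clean = list(),
      degraded = list(contig_count = 30, gap_count = 3,
                      missing_amino_acids = 6, missing_domains = 25,
                      rrna_profile = "half_min")))
  gq <- score_cohort(lapply(coh, `[[`, "assembly"),
                     lapply(coh, `[[`, "features"))
  genus <- gq$metadata$genus
  clean_tot <- gq$scores$standardized_total[genus == "clean"]
  deg_tot <- gq$scores$standardized_total[genus == "degraded"]
  expect_gt(min(clean_tot), max(deg_tot))
  d <- score_distribution(gq, genus, columns = "raw_combined")
  top_bin <- d[d$bin_upper == 1, ]
  expect_gt(top_bin$percent[top_bin$group == "clean"],
            top_bin$percent[top_bin$group == "degraded"])
})
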