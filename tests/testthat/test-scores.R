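metrics_of <- function(seq, name = "m") {
  compute_assembly_metrics(genome_assembly(name, c(c1 = seq)))
}

test_that("sequence quality score matches the penalty formula on worked cases", {
  cfg <- scoring_config()
  clean <- genome_assembly("clean", c(c1 = strrep("ACGT", 250000)))
  expect_equal(sequence_quality_score(compute_assembly_metrics(clean), "draft"), 1.0)

  # two clean 1 Mb contigs: one 10,000 bp contig penalty
  two <- genome_assembly("two", c(c1 = strrep("ACGT", 250000),
                                  c2 = strrep("ACGT", 250000)))
  expect_equal(sequence_quality_score(compute_assembly_metrics(two), "draft"),
               2000000 / 2010000)

  # complete status removes the contig penalty, multi-replicon scores 1.0
  three <- genome_assembly("rep3", c(c1 = strrep("ACGT", 500000),
                                     c2 = strrep("ACGT", 500000),
                                     c3 = strrep("ACGT", 250000)),
                           status = "complete")
  expect_equal(sequence_quality_score(compute_assembly_metrics(three), "complete"), 1.0)

  # one 15-N gap in a 1 Mb contig: one 10,000 bp gap penalty
  gapped <- genome_assembly("gap", c(c1 = paste0(strrep("ACGT", 125000),
                                                 strrep("N", 15),
                                                 strrep("ACGT", 125000))))
  expect_equal(sequence_quality_score(compute_assembly_metrics(gapped), "draft"),
               1000000 / 1010000)

  # complete genomes keep the gap penalty
  expect_equal(sequence_quality_score(compute_assembly_metrics(gapped), "complete"),
               1000000 / 1010000)

  # degenerate assembly: all N
  expect_warning(s <- sequence_quality_score(metrics_of(strrep("N", 50)), "draft"))
  expect_identical(s, 0)
})

test_that("sequence quality equals a character-by-character recomputation", {
  set.seed(2024)
  for (i in 1:20) {
    a <- random_assembly(sample(1:5, 1))
    status <- sample(c("draft", "complete"), 1)
    m <- compute_assembly_metrics(a)
    expect_equal(sequence_quality_score(m, status), brute_sequence_quality(a, status))
  }
})

test_that("sequence quality penalties are monotone and dilute with size", {
  base <- strrep("ACGT", 25000)  # 100 kb
  one <- metrics_of(base)
  two <- compute_assembly_metrics(genome_assembly("s", c(c1 = base, c2 = base)))
  expect_lt(sequence_quality_score(two, "draft"),
            sequence_quality_score(one, "draft"))
  gap <- metrics_of(paste0(base, strrep("N", 12), base))
  expect_lt(sequence_quality_score(gap, "draft"),
            sequence_quality_score(one, "draft"))

  # doubling every megabase-scale contig of a clean draft (same contig
  # count) moves the score by < 0.005: penalties are per contig, not per
  # base, so they dilute with genome size
  a5 <- genome_assembly("a5", setNames(rep(strrep("ACGT", 250000), 5), paste0("c", 1:5)))
  a5x2 <- genome_assembly("a5", setNames(rep(strrep("ACGT", 500000), 5), paste0("c", 1:5)))
  s1 <- sequence_quality_score(compute_assembly_metrics(a5), "draft")
  s2 <- sequence_quality_score(compute_assembly_metrics(a5x2), "draft")
  expect_lt(abs(s2 - s1), 0.005)
})

test_that("rRNA score applies the tier rules per molecule type", {
  cfg <- scoring_config()
  expect_equal(as.numeric(rrna_score(ideal_rrnas())), 1.0)
  expect_equal(as.numeric(rrna_score(ideal_rrnas()[0, ])), 0.1)

  # single 16S at 800 bp: above half the 1450 minimum, outside the window
  expect_equal(as.numeric(rrna_score(data.frame(molecule = "16S", length = 800))), 0.3)
  # over-long 16S keeps the 0.2 tier but is flagged
  over <- rrna_score(data.frame(molecule = "16S", length = 2400))
  expect_equal(as.numeric(over), 0.3)
  expect_identical(attr(over, "overlong"), "16S")
  # fragment below half-minimum earns the existence tier only
  expect_equal(as.numeric(rrna_score(data.frame(molecule = "16S", length = 700))), 0.2)
  # the best prediction per type wins; extra copies do not add
  multi <- data.frame(molecule = c("16S", "16S", "16S"), length = c(700, 1550, 90))
  expect_equal(as.numeric(rrna_score(multi)), 0.4)
})

test_that("tRNA score subtracts per missing amino acid down to the floor", {
  expect_equal(trna_score(trna_covering(20)), 1.0)
  expect_equal(trna_score(trna_covering(17)), 0.7)
  expect_equal(trna_score(trna_covering(11)), 0.1)  # 9 missing hits the floor
  expect_equal(trna_score(trna_covering(0)), 0.1)
  # pseudo predictions never demonstrate coverage
  pseudo_met <- data.frame(amino_acid = "Met", anticodon = "CAT", pseudo = TRUE)
  full <- rbind(trna_covering(20), pseudo_met)
  missing_met <- full[full$amino_acid != "Met" | full$pseudo, ]
  expect_equal(trna_score(missing_met), 0.9)
  # SeC and undetermined types do not count toward the 20
  sec_only <- data.frame(amino_acid = c("SeC", "other"),
                         anticodon = c("TCA", NA), pseudo = FALSE)
  expect_equal(trna_score(sec_only), 0.1)
})

test_that("essential-gene score subtracts per missing domain down to the floor", {
  cfg <- scoring_config()
  expect_equal(essential_gene_score(domain_hits_present(102), cfg), 1.0)
  expect_equal(essential_gene_score(domain_hits_present(92), cfg), 0.90)
  expect_equal(essential_gene_score(domain_hits_present(7), cfg), 0.1)  # clamped
  expect_equal(essential_gene_score(domain_hits_present(0), cfg), 0.1)
  # copies of one domain do not add
  dup <- domain_hits_present(92)
  dup <- rbind(dup, dup)
  expect_equal(essential_gene_score(dup, cfg), 0.90)
  # versioned accessions match their family
  versioned <- domain_hits_present(102)
  versioned$domain_accession <- paste0(versioned$domain_accession, ".14")
  expect_equal(essential_gene_score(versioned, cfg), 1.0)
})

test_that("component scores sit on their lattices and combine by the mean", {
  cfg <- scoring_config()
  set.seed(31)
  for (i in 1:15) {
    rr <- as.numeric(rrna_score(random_feature_set()$rrnas, cfg))
    expect_true(rr >= 0.1 && rr <= 1.0)
    expect_equal(rr, round(rr, 1))  # steps of 0.1
    tr <- trna_score(trna_covering(sample(0:20, 1)))
    expect_true(any(abs(tr - seq(0.1, 1.0, 0.1)) < 1e-12))
    es <- essential_gene_score(domain_hits_present(sample(0:102, 1)), cfg)
    expect_true(es >= 0.1 && es <= 1.0)
  }
  # adding a feature never decreases a feature score
  expect_gte(as.numeric(rrna_score(rbind(ideal_rrnas()[1, ],
                                         data.frame(molecule = "16S", length = 1500)))),
             as.numeric(rrna_score(ideal_rrnas()[1, ])))
  expect_gte(trna_score(trna_covering(12)), trna_score(trna_covering(11)))
  expect_gte(essential_gene_score(domain_hits_present(50), cfg),
             essential_gene_score(domain_hits_present(49), cfg))

  expect_equal(raw_combined(list(sequence_quality = 0, rrna = 0.1,
                                 trna = 0.1, essential = 0.1)), 0.075)
  expect_equal(raw_combined(list(sequence_quality = 1, rrna = 1,
                                 trna = 1, essential = 1)), 1.0)
  # mean is permutation-invariant in the four components
  expect_equal(raw_combined(list(sequence_quality = 0.4, rrna = 0.9,
                                 trna = 0.6, essential = 0.2)),
               raw_combined(list(sequence_quality = 0.2, rrna = 0.4,
                                 trna = 0.9, essential = 0.6)))
})

test_that("score_genome assembles the four components and their mean", {
  p <- simulation_params(seed = 11, genome_size = 50000, contig_count = 3,
                         missing_amino_acids = 2, missing_domains = 5,
                         rrna_profile = c(`5S` = "ideal", `16S` = "half_min",
                                          `23S` = "absent"))
  asm <- simulate_assembly(p)
  fs <- simulate_features(p)
  sc <- score_genome(asm, fs)
  expect_equal(sc$sequence_quality, 50000 / 70000)
  expect_equal(sc$rrna, 0.1 + 0.3 + 0.2)
  expect_equal(sc$trna, 0.8)
  expect_equal(sc$essential, 0.95)
  expect_equal(sc$raw_combined,
               mean(c(sc$sequence_quality, sc$rrna, sc$trna, sc$essential)))
})
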