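#' Parameters for the synthetic genome and feature generator
#'
#' Describes a synthetic genome by its score-relevant degradation modes:
#' fragmentation (contig count), N-gaps, non-ACGT bases, missing amino-acid
#' coverage, pseudo-tRNAs, rRNA length profiles and missing essential
#' domains. Count-valued degradation is placed constructively — the realized
#' contig, gap, bad-base, missing-amino-acid and missing-domain counts equal
#' the parameters exactly — so tests can assert exact scores; only base
#' composition is stochastic.
#'
#' @param seed Integer seed governing all randomness.
#' @param genome_size Number of non-N bases (bp). Gaps add
#'   `gap_count * gap_length` N bases on top.
#' @param contig_count Number of contigs the sequence is split into.
#' @param gap_count Number of N runs to place (each of length `gap_length`).
#' @param gap_length Length of each N run; must reach the configured
#'   `gap_min_run` to register as a gap.
#' @param bad_base_rate Fraction of non-N bases replaced by an IUPAC
#'   ambiguity code (`R`); realized count is
#'   `round(bad_base_rate * genome_size)`.
#' @param gc_content Target GC fraction of good bases.
#' @param missing_amino_acids How many of the 20 standard amino acids get no
#'   non-pseudo tRNA (0-20).
#' @param pseudo_trna_count Number of additional pseudo-tRNA predictions.
#' @param rrna_profile Character vector for molecules `5S`, `16S`, `23S`
#'   (recycled if length 1) with values `"absent"`, `"short"` (at most half
#'   the ideal minimum), `"half_min"` (between half the minimum and the
#'   minimum), `"ideal"` (inside the ideal window) or `"overlong"` (above
#'   the ideal maximum).
#' @param missing_domains How many essential-panel domains get no hit.
#' @param rare_anticodon_probability Per-tRNA probability of drawing a rare
#'   (A-starting, non-ACG) anticodon where the amino acid admits one.
#' @param gene_count Number of protein genes to simulate; default scales as
#'   one gene per kilobase.
#' @param gene_mean_length Mean simulated gene length (bp).
#' @param status Assembly status, `"draft"` or `"complete"`.
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(seed = 1L,
                              genome_size = 4e6,
                              contig_count = 1L,
                              gap_count = 0L,
                              gap_length = 50L,
                              bad_base_rate = 0,
                              gc_content = 0.5,
                              missing_amino_acids = 0L,
                              pseudo_trna_count = 0L,
                              rrna_profile = c(`5S` = "ideal", `16S` = "ideal", `23S` = "ideal"),
                              missing_domains = 0L,
                              rare_anticodon_probability = 0,
                              gene_count = NULL,
                              gene_mean_length = 900,
                              status = c("draft", "complete")) {
  status <- match.arg(status)
  if (length(rrna_profile) == 1L) {
    rrna_profile <- stats::setNames(rep(rrna_profile, 3L), c("5S", "16S", "23S"))
  }
  if (is.null(names(rrna_profile))) names(rrna_profile) <- c("5S", "16S", "23S")
  stopifnot(
    length(seed) == 1L, is.finite(seed),
    genome_size >= 1, contig_count >= 1, gap_count >= 0, gap_length >= 1,
    bad_base_rate >= 0, bad_base_rate <= 1,
    gc_content >= 0, gc_content <= 1,
    missing_amino_acids >= 0, missing_amino_acids <= 20,
    pseudo_trna_count >= 0,
    all(names(rrna_profile) %in% c("5S", "16S", "23S")),
    all(rrna_profile %in% c("absent", "short", "half_min", "ideal", "overlong")),
    missing_domains >= 0,
    rare_anticodon_probability >= 0, rare_anticodon_probability <= 1
  )
  structure(
    list(seed = as.integer(seed), genome_size = genome_size,
         contig_count = as.integer(contig_count),
         gap_count = as.integer(gap_count), gap_length = as.integer(gap_length),
         bad_base_rate = bad_base_rate, gc_content = gc_content,
         missing_amino_acids = as.integer(missing_amino_acids),
         pseudo_trna_count = as.integer(pseudo_trna_count),
         rrna_profile = rrna_profile,
         missing_domains = as.integer(missing_domains),
         rare_anticodon_probability = rare_anticodon_probability,
         gene_count = gene_count, gene_mean_length = gene_mean_length,
         status = status),
    class = "simulation_params"
  )
}

# run code under a given seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  code
}

# stable per-stream seed derivation; keeps results order-independent across
# cohort members and below 2^31 (R integers are 32-bit)
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) %% 2147483587 * 48271 + stream * 104729) %% 2147483587)
}

#' Simulate a genome assembly
#'
#' Deterministic given `params$seed`. Good bases are drawn A/C/G/T at the
#' target GC; `round(bad_base_rate * genome_size)` positions are replaced by
#' `R`; the sequence is split into `contig_count` contigs of near-equal
#' size; `gap_count` N runs of `gap_length` are placed at interior
#' positions, round-robin across contigs and always flanked by non-N bases,
#' so the realized contig, gap and bad-base counts equal the parameters
#' exactly.
#'
#' @param params A [simulation_params()].
#' @param name Assembly name.
#' @param config A [scoring_config()] (used to check `gap_length` against
#'   `gap_min_run`).
#' @return A [genome_assembly()].
#' @export
simulate_assembly <- function(params, name = sprintf("sim_%d", params$seed),
                              config = scoring_config()) {
  stopifnot(inherits(params, "simulation_params"))
  if (params$gap_count > 0L && params$gap_length < config$gap_min_run) {
    stop("gap_length (", params$gap_length, ") is below gap_min_run (",
         config$gap_min_run, "); gaps would not register")
  }
  if (params$genome_size < params$contig_count) {
    stop("genome_size smaller than contig_count")
  }
  with_local_seed(derive_seed(params$seed, 1L), {
    n <- params$genome_size
    gc <- params$gc_content
    base <- sample(c("A", "T", "G", "C"), n, replace = TRUE,
                   prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
    n_bad <- round(params$bad_base_rate * n)
    if (n_bad > 0L) base[sample.int(n, n_bad)] <- "R"
    # near-equal contig sizes
    cuts <- round(seq(0, n, length.out = params$contig_count + 1L))
    sizes <- diff(cuts)
    gaps_per_contig <- tabulate(
      rep_len(seq_len(params$contig_count), params$gap_count),
      nbins = params$contig_count)
    seqs <- character(params$contig_count)
    for (i in seq_len(params$contig_count)) {
      chunk <- base[(cuts[i] + 1L):cuts[i + 1L]]
      g <- gaps_per_contig[i]
      if (g == 0L) {
        seqs[i] <- paste(chunk, collapse = "")
        next
      }
      if (length(chunk) < g + 1L) {
        stop("infeasible: contig ", i, " too short (", length(chunk),
             " bases) to hold ", g, " interior gap(s)")
      }
      # split into g+1 non-empty segments and interleave N runs
      seg_cuts <- round(seq(0, length(chunk), length.out = g + 2L))
      segs <- lapply(seq_len(g + 1L), function(k) {
        chunk[(seg_cuts[k] + 1L):seg_cuts[k + 1L]]
      })
      gap_run <- strrep("N", params$gap_length)
      seqs[i] <- paste(vapply(segs, paste, character(1), collapse = ""),
                       collapse = gap_run)
    }
    names(seqs) <- sprintf("contig_%03d", seq_along(seqs))
    genome_assembly(name, seqs, status = params$status,
                    metadata = list(simulated = TRUE, seed = params$seed))
  })
}

#' Simulate a feature set
#'
#' Deterministic given `params$seed`. Produces non-pseudo tRNAs covering
#' exactly `20 - missing_amino_acids` standard amino acids (which amino
#' acids are missing is drawn from the seed), `pseudo_trna_count` pseudo
#' predictions, rRNA predictions with lengths drawn per `rrna_profile`, hits
#' for all but exactly `missing_domains` of the essential panel, and
#' `gene_count` protein genes. Anticodons are drawn from the codons of each
#' tRNA's amino acid, avoiding the rare set except with probability
#' `rare_anticodon_probability`.
#'
#' @param params A [simulation_params()].
#' @param genome_name Name recorded in the feature set.
#' @param config A [scoring_config()] supplying the essential panel and
#'   rRNA windows.
#' @return A [feature_set()].
#' @export
simulate_features <- function(params, genome_name = sprintf("sim_%d", params$seed),
                              config = scoring_config()) {
  stopifnot(inherits(params, "simulation_params"))
  essential <- config$essential_domains
  if (params$missing_domains > length(essential)) {
    stop("missing_domains (", params$missing_domains,
         ") exceeds panel size (", length(essential), ")")
  }
  with_local_seed(derive_seed(params$seed, 2L), {
    rare <- default_rare_anticodons()
    covered <- sort(sample(STANDARD_AMINO_ACIDS,
                           20L - params$missing_amino_acids))
    pick_anticodon <- function(aa) {
      opts <- AA_ANTICODONS[[aa]]
      rare_opts <- intersect(opts, rare)
      safe_opts <- setdiff(opts, rare)
      if (length(rare_opts) > 0L &&
          stats::runif(1) < params$rare_anticodon_probability) {
        sample(rare_opts, 1L)
      } else if (length(safe_opts) > 0L) {
        sample(safe_opts, 1L)
      } else {
        sample(opts, 1L)
      }
    }
    trnas <- if (length(covered) > 0L) {
      data.frame(amino_acid = covered,
                 anticodon = vapply(covered, pick_anticodon, character(1)),
                 pseudo = FALSE, stringsAsFactors = FALSE)
    } else empty_trnas()
    if (params$pseudo_trna_count > 0L) {
      paa <- sample(STANDARD_AMINO_ACIDS, params$pseudo_trna_count, replace = TRUE)
      trnas <- rbind(trnas, data.frame(
        amino_acid = paa,
        anticodon = vapply(paa, pick_anticodon, character(1)),
        pseudo = TRUE, stringsAsFactors = FALSE))
    }
    rrnas <- empty_rrnas()
    for (mol in names(params$rrna_profile)) {
      prof <- params$rrna_profile[[mol]]
      if (prof == "absent") next
      rng <- config$rrna_ranges[config$rrna_ranges$molecule == mol, ]
      lo <- rng$min_ideal; hi <- rng$max_ideal
      len <- switch(prof,
        ideal = sample(lo:hi, 1L),
        half_min = sample((floor(lo / 2) + 1L):(lo - 1L), 1L),
        short = sample(seq_len(floor(lo / 2)), 1L),
        overlong = sample((hi + 1L):round(1.5 * hi), 1L))
      rrnas <- rbind(rrnas, data.frame(molecule = mol, length = len,
                                       stringsAsFactors = FALSE))
    }
    present <- if (params$missing_domains > 0L) {
      sort(sample(essential, length(essential) - params$missing_domains))
    } else essential
    domains <- if (length(present) > 0L) {
      data.frame(domain_accession = present,
                 gene_id = sprintf("gene_%04d", seq_along(present)),
                 stringsAsFactors = FALSE)
    } else empty_domains()
    n_genes <- if (is.null(params$gene_count)) {
      max(1L, round(params$genome_size / 1000))
    } else params$gene_count
    lens <- pmax(90, round(stats::rnorm(n_genes, params$gene_mean_length, 150)))
    genes <- data.frame(id = sprintf("gene_%04d", seq_len(n_genes)),
                        length_nt = lens, stringsAsFactors = FALSE)
    feature_set(genome_name, trnas = trnas, rrnas = rrnas,
                genes = genes, domains = domains)
  })
}

#' Simulate a cohort of genomes with features and metadata
#'
#' Builds `n` genomes from a template parameter set. Per-genome randomness
#' derives from a stable split of the master seed, so each genome's content
#' depends only on the seed and its index, not on cohort membership order.
#' Genomes are assigned to groups round-robin; per-group parameter overrides
#' (and an optional per-genome `vary` function) let tests construct cohorts
#' with known group-wise quality differences.
#'
#' @param n Number of genomes.
#' @param template A [simulation_params()] used for every genome.
#' @param seed Master seed.
#' @param groups `NULL` (one group `"cohort"`), a character vector of group
#'   names, or a named list `group -> list of parameter overrides`.
#' @param vary Optional `function(i)` returning a list of parameter
#'   overrides for genome `i` (applied after group overrides).
#' @param config A [scoring_config()].
#' @return List of length `n`; each element is a list with `assembly`
#'   (a `genome_assembly` whose metadata records `genus` = group and
#'   `source` = `"simulated"`) and `features` (a `feature_set`).
#' @export
simulate_cohort <- function(n, template = simulation_params(), seed = 1L,
                            groups = NULL, vary = NULL,
                            config = scoring_config()) {
  stopifnot(n >= 1)
  if (is.null(groups)) groups <- "cohort"
  overrides <- list()
  if (is.list(groups)) {
    overrides <- groups
    group_names <- names(groups)
  } else {
    group_names <- as.character(groups)
  }
  assign_group <- rep_len(group_names, n)
  lapply(seq_len(n), function(i) {
    g <- assign_group[i]
    ov <- if (!is.null(overrides[[g]])) overrides[[g]] else list()
    if (!is.null(vary)) ov <- utils::modifyList(ov, vary(i))
    p <- utils::modifyList(unclass(template), ov)
    p$seed <- derive_seed(seed, i)
    p <- do.call(simulation_params, p)
    nm <- sprintf("%s_%03d", g, i)
    assembly <- simulate_assembly(p, name = nm, config = config)
    assembly$metadata$genus <- g
    assembly$metadata$source <- "simulated"
    list(assembly = assembly, features = simulate_features(p, nm, config))
  })
}

# amino acid (three-letter) -> admissible anticodons (DNA alphabet),
# derived from the standard genetic code
build_aa_anticodons <- function() {
  code <- Biostrings::GENETIC_CODE
  codons <- chartr("U", "T", names(code))
  one2three <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
                 Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
                 L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
                 S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val")
  revcomp <- function(x) {
    vapply(strsplit(chartr("ACGT", "TGCA", x), ""), function(ch) {
      paste(rev(ch), collapse = "")
    }, character(1))
  }
  keep <- unname(code) %in% names(one2three)
  split(revcomp(codons[keep]), unname(one2three[unname(code)[keep]]))
}

AA_ANTICODONS <- NULL  # filled at load; see .onLoad

.onLoad <- function(libname, pkgname) {
  AA_ANTICODONS <<- build_aa_anticodons()
}
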