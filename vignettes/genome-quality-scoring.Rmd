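---
title: "Scoring genome assemblies for completeness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring genome assemblies for completeness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genomeqc)
```

## The problem

Most prokaryotic genomes in public repositories are drafts: collections of
contigs with assembly gaps, ambiguous bases, and — at the low end — missing
genes. When an analysis spans thousands of genomes there is no reference to
align against, so quality must be estimated from the assembly itself.
`genomeqc` does this with four component scores that each interrogate a
different, largely independent notion of completeness, and combines them.
This vignette explains the model behind each component, the tunable
parameters, the cohort-combination step, what the synthetic generator does
and does not emulate, and the numerical and design choices made where more
than one reading was defensible.

## The four components

### Sequence quality

An assembly with `g` good bases (A, C, G, T), `b` bad bases (any IUPAC
ambiguity code — everything except A/C/G/T/N), `c` contigs and `k` N-gaps
scores

$$S_{seq} = \frac{g}{g + b + P_c \cdot \max(0, c-1) \cdot [\text{draft}] + P_g \cdot k}$$

with both penalties defaulting to $P_c = P_g = 10{,}000$ bp. The rationale:
gene prediction loses on average about one gene (≈ 1 kb) per contig edge,
and an assembly capturing only 90% of genes should not look high-quality,
so the missing-bases penalty is inflated tenfold. A gap — a run of N of at
least `gap_min_run` (default 10) consecutive bases — breaks the sequence
exactly like a contig boundary and carries the same penalty. Genomes whose
status is *complete* are exempt from the contig penalty only: their extra
contigs are taken to be additional chromosomes or plasmids, but gaps and
bad bases still count against them.

Three details of the base accounting deserve stating explicitly:

* N runs shorter than `gap_min_run` are "loose" Ns: neither good nor bad,
  they inflate only the total size. This is the literal reading of the
  denominator definition (bad = anything except A, C, T, G, or N).
* Runs of N never span contig boundaries; each contig is scanned
  independently, since contigs are independent sequences.
* Sequences are uppercased on ingest, so soft-masked bases count as good:
  masking is annotation, not sequence quality. For the gap-run threshold we
  note the source material describes it variously as "over 10 bp" and "10
  or more N's"; the score definition itself uses the inclusive reading, so
  the default is ≥ 10, and the constant is exposed as `gap_min_run` rather
  than hard-coded.

### rRNA

The score starts at 0.1 — an empty prediction set cannot be distinguished
from a predictor failure, so the floor is deliberately above zero — and
adds, per molecule type, 0.3 for a prediction inside the ideal length
window, else 0.2 for one longer than half the window minimum, else 0.1 for
any prediction at all. The windows (5S 100–120, 16S 1450–1700, 23S
2900–3500 bp) bracket the full-length molecules, the 23S window broadened
for intron-bearing genes. When several copies of one molecule are
predicted — multi-copy rRNA operons are the norm — the best copy decides
the tier: one full-length copy demonstrates completeness.

Over-long predictions (beyond the window maximum) are a known predictor
failure mode, usually indicating embedded Ns, atypical regions or
low-GC-driven weakness. The tier rules are applied literally, so such a
prediction still earns the 0.2 tier, but `rrna_score()` flags the molecule
in an `overlong` attribute which the score card surfaces, because whether
to demote these is a judgement the scorer should expose rather than make
silently.

### tRNA

Every genome needs at least one tRNA per standard amino acid, and tRNAs are
conserved and easy to find, so absence is informative. The score starts at
1.0 and subtracts 0.1 per uncovered amino acid, floored at 0.1 (reached at
nine or more missing). Coverage is decided by the predictor's amino-acid
call, never by translating the anticodon — wobble rules would second-guess
the predictor. Pseudo-tRNA predictions never demonstrate coverage, and
non-standard types (selenocysteine, undetermined) do not count toward the
20, though they are counted in the anticodon analytics.

### Essential genes

A panel of universal protein families — Pfam-A domains found in ≥ 99% of
finished bacterial and archaeal genomes — proxies gene-level completeness.
The score starts at 1.0 and subtracts 0.01 per missing panel domain,
floored at 0.1. Presence is per distinct version-stripped accession
(`PF00312.14` ≡ `PF00312`): the score counts missing families, not copies.
The packaged 102-entry panel is a synthetic reconstruction built from
near-universal translation, transcription and replication families; it is
a configuration file, not a claim — `scoring_config(essential_domains =
...)` accepts any accession list, and the scorer only cares about the
panel's size and membership. No E-value threshold is applied when reading
HMMER hits: the upstream search's own reporting thresholds are respected,
and an optional explicit cutoff (`max_evalue`) is available but off by
default, so no hidden filter is baked in.

## Combining scores

For a single genome the combined score is the plain mean of the four
components. For a cohort, each component is standardized
($z = (x-\mu)/\sigma$), the z-scores averaged per genome, and the averages
min–max rescaled to [0, 1]. Choices made here, where the description of
the procedure left room:

* **Population σ**, not sample σ: the cohort being scored is the whole
  universe of interest, not a sample from one.
* A zero-variance component contributes $z = 0$ for every genome: a
  constant column carries no ranking information, and dropping it (rather
  than dividing by zero) is the only continuous choice.
* "Rescaled to a minimum of zero and a maximum of one" is implemented as
  min–max rescaling of the averaged z-scores — the only transform
  consistent with that sentence without extra assumptions.
* Cohorts of one, and degenerate cohorts whose averaged z-scores are all
  identical, fall back to the raw mean. Standardization re-ranks nothing
  in either case, and for a single genome the raw mean is the recommended
  score.

Standardization changes ranks very little in practice; the test suite
checks Spearman agreement ≥ 0.9 between raw and standardized totals on
simulated 50-genome cohorts.

## Deduplication and size filtering

Cross-repository duplicates cannot be caught by name matching (strain
names drift), so assemblies are fingerprinted: MD5 of each contig's
uppercase sequence bytes, digests sorted lexicographically, joined with
commas, and the joined string hashed again. Sorting makes the fingerprint
contig-order-invariant; ids and descriptions are excluded because names
differ where sequences do not. This catches only byte-identical assemblies
— one base differs and the fingerprint differs; near-duplicate detection
is out of scope. Whether an upstream pipeline hashed raw bytes, uppercase
text or line-wrapped records is generally unknowable, so cross-pipeline
fingerprint equality is not promised; within-package fingerprints are
stable and tested.

Total assembly size classifies obvious non-genomes: strictly below
138,500 bp the record is a stray plasmid, strictly above 18,000,000 bp it
is eukaryotic; both thresholds are retained-inclusive and configurable.

## The synthetic generator

`simulate_assembly()` / `simulate_features()` / `simulate_cohort()` build
genomes by their score-relevant structure: contig count, N-gap count and
length, bad-base count, GC content, amino-acid coverage, pseudo-tRNA
count, per-molecule rRNA length profile (absent / short / half-window /
ideal / over-long), missing essential domains, and rare-anticodon
probability. Count-valued degradation is placed *constructively* — the
realized counts equal the parameters exactly, with gaps placed at interior
positions flanked by non-N bases so runs neither merge nor touch contig
ends — which lets unit tests assert exact analytic scores instead of
tolerances. Only base composition is stochastic. A single integer seed
governs everything; per-genome streams are derived by a stable splitting
function of (seed, index), so genome *i* is identical regardless of cohort
size or membership order.

Default parameters describe a clean 4 Mb single-contig draft at GC 0.5 —
a typical bacterial genome — with full feature complement; every
degradation is opt-in. Tests and examples use 20–300 kb genomes: all four
component scores depend on counts and penalties, not on absolute size
(the sequence-quality penalties dilute with size, which is itself a tested
property), so small genomes exercise the same arithmetic at a fraction of
the cost, and the test suite states its sizes explicitly.

What the generator does **not** emulate: sequence homology (genes and
domains are declared in feature tables, not encoded in the DNA), read- or
assembly-graph-level error processes, real codon usage, contig length
distributions of real assemblers, or correlated failure modes (e.g. low GC
degrading rRNA prediction). Passing tests therefore demonstrate that the
scoring arithmetic, bookkeeping and cohort statistics are correct — not
that the scores are well-calibrated against any particular repository's
genomes. Calibration claims require real assemblies and real predictor
outputs, which enter through the adapters.

## Adapters and formats

Predictions are parsed from the standard outputs of the tools the scoring
scheme was designed around — tRNAscan-SE tabular, RNAmmer GFF2, Prodigal
GFF3, HMMER3 `--domtblout` — or from a native sectioned TSV
(`read_feature_table()` / `write_feature_table()`, round-trip-tested) so
the scorer can run with no external tools. Coordinates are 1-based
inclusive throughout and lengths are always derived as
`end − start + 1`, never read from attributes. The adapters are
mode-agnostic with respect to how the predictors were invoked. Running the
predictors themselves is out of scope.

## Numerical conventions

Scores are computed in double precision and never rounded internally.
Score cards display two decimals. Percentages in the rare-anticodon table
display with two significant digits, exact halves rounded toward zero, and
at most one decimal place — the convention that reproduces the published
genus-table values (87 from 28/32, 0.1 from 3/2177, 44 from 150/338);
standard round-half-even rounding would print 88 and 0.14 for the first
two. Score-distribution bins are right-closed (a bin is labelled by the
largest value in its range) and default bin edges are computed as
`(0:10)/10` so edge values compare exactly.

## Anticodon analytics

A genome can carry tRNAs with up to 62 distinct anticodons: the reverse
complements of the 61 sense codons plus TCA, the selenocysteine anticodon
read against recoded UGA. The rare-anticodon set is defined structurally —
the 16 anticodons beginning with A (pairing codons ending in U) minus ACG,
the one A-starting anticodon commonly predicted — rather than as a fixed
list, and is overridable. `anticodon_frequency()` counts non-pseudo tRNAs
(optional types included); `rare_anticodon_by_group()` counts a genome
once if any of its non-pseudo tRNAs carries a rare anticodon.

## Known limitations

* Completeness only: contamination, misidentification, and base-level
  accuracy are invisible to all four components; a perfectly assembled
  genome of the wrong organism scores 1.0.
* The essential-domain panel is as good as its list; lineages that
  genuinely lack panel families (reduced endosymbionts) score low for
  biological rather than technical reasons — the same genomes also score
  low on tRNA coverage, which is informative but not a defect measure.
* Fingerprints catch byte-identical duplicates only.
* The `complete` status must be supplied (manifest or constructor); it is
  never inferred from the sequence, because inference from contig
  structure is unreliable across repositories.
* N-run and size thresholds, penalties and windows are conventions, not
  fitted parameters; they are exposed in `scoring_config()` and the
  defaults reproduce the published scheme.
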