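Package: genomeqc
Title: Completeness Quality Scores for Prokaryotic Genome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns completeness quality scores to prokaryotic genome
    assemblies from four components: sequence quality (contig and N-gap
    penalties over good bases), full-length 5S/16S/23S rRNA presence, tRNA
    coverage of the 20 standard amino acids, and presence of a configurable
    panel of universal essential Pfam-A domains. Combines the components as
    a raw mean or as a cohort-standardized (z-score averaged, min-max
    rescaled) total. Includes adapters for tRNAscan-SE, RNAmmer, Prodigal
    and HMMER3 outputs, MD5 checksum-of-checksums assembly deduplication,
    size-based filtering, cohort analytics (anticodon frequencies, rare
    anticodon incidence by group, gene length and density, score
    distributions), and a seeded synthetic fixture generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    digest,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
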