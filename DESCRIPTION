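Package: dinomir
Title: Small RNA Discovery, Differential Expression and Enrichment for
    Non-Model Algal Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale re-implementation of a small RNA sequencing
    analysis pipeline for non-model unicellular algae. Cleans and collapses
    18-25 nt small RNA reads from two libraries, partitions them into
    contaminant non-coding RNA classes, matches known miRNAs with
    end-shift/substitution variant notation, discovers novel miRNA hairpin
    precursors on transcriptome contigs with an eleven-criterion stem-loop
    acceptance test over a maximum-base-pairing folder (or externally
    supplied Vienna structures), tests two-library differential expression
    with Fisher exact and chi-square 2x2 statistics on per-million
    normalized counts, performs hypergeometric term enrichment over
    precomputed target-gene lists, and computes comparative-threshold
    (2^-ddCt) qPCR relative expression. A seeded synthetic-data generator
    plants miRNA hairpins, contaminants and junk reads with known
    between-library abundance ratios and emits a truth manifest so every
    stage is verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
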