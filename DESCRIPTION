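Package: rnasedep
Title: Tiling-Array Analysis of Transcript Abundance Under RNase Depletion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of strand-specific tiling-array experiments
    that measure how depletion of the essential Bacillus subtilis
    ribonucleases Y, J1, and III changes transcript abundance. Provides a
    seeded synthetic-data generator with known ground truth (genome
    annotation, 22-nt tiled probe designs, hybridization signals with probe
    affinity and sample shift, rifampicin-chase decay time courses),
    probe-level signal decomposition and gene aggregation, stratified
    least-variant-set loess normalization, a per-gene depletion linear model
    with Benjamini-Hochberg q-values and U/D/- fold-change profiles,
    detection and classification of transcribed segments (5'UTRs, antisense
    and independent RNAs), Fisher-exact functional-category enrichment with
    Bonferroni control, first-order degradation-pathway kinetics with
    half-life fitting, and genome-browser track export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    jsonlite,
    yaml,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    optparse
Config/testthat/edition: 3
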