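Package: ciberseq
Title: Processing and Differential Analysis of Dual-Barcoded CRISPRi
    Expression-Reporter Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end processing of dual-barcoded CRISPRi
    expression-reporter (CiBER-seq) screens: construction of the
    barcode-to-sgRNA lookup table from long reads of the plasmid library,
    extraction of barcodes and unique molecular identifiers (UMIs) from
    short amplicon reads, directional collapse of sequencing-error barcode
    variants and UMI deduplication to molecule counts, tabulation into
    count matrices with abundance filtering and per-construct aggregation,
    and negative-binomial Wald tests of condition and reporter-channel
    contrasts with control-screen baseline normalization. A synthetic
    screen generator with known ground truth makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    Biostrings,
    SummarizedExperiment,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
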