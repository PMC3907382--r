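Package: cghcnv
Title: Copy Number Variant Discovery from Two-Channel Array CGH
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for discovering copy number variants
    (CNVs) from two-channel array comparative genomic hybridization (aCGH)
    data: spatial LOESS correction of array-position artifacts, q-spline
    quantile normalization of the dye channels, optimal least-squares
    segmentation of log2-ratio tracks by dynamic programming, threshold-based
    gain/loss calling, merging of per-sample calls into copy number variable
    regions (CNVRs) with population summaries and gene annotation, and qPCR
    validation via the 2^-ddCt method. A seeded synthetic-array simulator
    (tiling probe designs, planted CNVs, dye bias, spatial gradients,
    self-self hybridizations) makes every stage testable without microarray
    hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
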