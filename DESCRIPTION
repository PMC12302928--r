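Package: flavoromics
Title: Integrated Metabolomics and Flavoromics Analysis of Multi-Group Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for joint analysis of non-volatile
    metabolite and volatile organic compound (VOC) intensity tables from
    multi-group designs, as produced by LC-MS and GCxGC-TOF MS profiling of
    food matrices. Covers peak-level quality control (signal-to-noise and
    library-similarity thresholds), internal-standard semi-quantification,
    missingness filtering and half-minimum imputation, van den Dool-Kratz
    retention-index calibration against an n-alkane ladder with tolerance-based
    identity confirmation, principal component analysis and orthogonal partial
    least-squares discriminant analysis (OPLS-DA) with variable importance in
    projection (VIP) and cross-validated Q2, differential-feature screening
    with Benjamini-Hochberg control, relative odor activity value (ROAV)
    scoring of aroma contribution, VOC chemical-class composition and Venn
    partitioning, VOC-sensory attribute bipartite networks, Spearman
    correlation of VOCs against metabolites, and hypergeometric pathway
    over-representation. Includes a synthetic-study generator emulating a
    three-breed design so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
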