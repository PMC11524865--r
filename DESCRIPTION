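Package: orthoexpress
Title: Cross-Species Hair-Cell Transcriptome Comparison and Electromotility Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing inner-ear hair-cell transcriptomes across a
    duplicated (teleost) and a non-duplicated (mammalian) genome. Builds the
    cross-species homology graph from Biomart-style ortholog exports,
    classifies one-to-one, one-to-many and many-to-many relationships, applies
    high-confidence score thresholds, and collapses redundant genes on the
    non-duplicated side. Lifts per-gene RPKM/FDR presence calls to ortholog
    groups, computes paralog-aware Venn partitions of cell-type expression,
    ranked top-N and uniquely-expressed gene tables, a transparent
    negative-binomial Wald differential-expression test with
    Benjamini-Hochberg correction, and hypergeometric gene-set
    over-representation against GMT collections. Also implements the
    voltage-clamp electromotility analysis used for outer hair cells:
    two-state Boltzmann motility and derivative-of-Boltzmann nonlinear
    capacitance (NLC) models with least-squares fitting, dual-sine
    FFT-admittance membrane capacitance estimation, and voltage-dependence
    classification. A seeded synthetic-data generator emulates all inputs so
    the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
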