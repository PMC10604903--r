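Package: regmtlmm
Title: Regularized Multi-Trait Linear Mixed Models for GWAS and Genomic
    Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Joint modelling of many traits and genome-wide markers in
    structured populations. Fits multi-trait linear mixed models with a
    kinship-structured genetic covariance by penalized maximum likelihood,
    combining an L1 (variable-selection) penalty with an optional convex
    trait-clustering penalty, and optimizing with accelerated proximal
    gradient steps in the kinship eigenbasis. Includes single-marker
    single-trait and multi-trait association scans with
    Benjamini-Hochberg false-discovery control, genomic-selection
    cross-validation with GEBV prediction and an RR-BLUP baseline, and a
    matrix-variate phenotype simulator with structured synthetic
    genotypes for QTN-detection benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    glmnet,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
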