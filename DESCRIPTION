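Package: famGS
Title: Genomic Selection Evaluation for Multi-Family Aquaculture Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation-driven evaluation of genomic selection for growth
    traits in multi-family breeding populations such as full-sib shrimp
    cohorts. Provides a gene-drop simulator of full-sib families with
    additive polygenic traits, SNP quality control and imputation, VanRaden
    genomic relationship and identity-by-state kinship matrices, spectral
    REML estimation of marker-based heritability, native RR-BLUP, BayesA
    and Bayesian LASSO marker-effect models with Gibbs samplers, classical
    multidimensional scaling with k-means population stratification, and
    cross-validation designs probing marker density and reference/validation
    relatedness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    Rcpp,
    yaml,
    cluster,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
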