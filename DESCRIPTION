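Package: stabgen
Title: Stability Analysis and Genomic Prediction for Multi-Environment Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for selecting crop genotypes that combine high phenotypic
    performance with environmental stability across multi-environment trials.
    Provides fixed-effects adjustment of plot-level data to genotype means
    (eBLUEs) under randomized complete block designs, AMMI and
    Finlay-Wilkinson stability indices, Bayesian whole-genome regression
    (Bayesian ridge and BayesB spike-and-slab Gibbs samplers) with single-,
    across- and multi-population parameterizations, k-fold cross-validation
    of traits and stability metrics, performance-by-stability co-selection,
    and a synthetic multi-environment trial generator for end-to-end
    validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
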