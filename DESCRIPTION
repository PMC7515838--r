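Package: cogslope
Title: Polygenic Prediction of Cognitive Level and Slope via Factors-of-Curves Growth Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying polygenic-score prediction of the level and
    rate of change of general cognitive ability in longitudinal ageing
    cohorts. Implements polygenic scoring from GWAS summary statistics
    (allele harmonization, greedy LD clumping, p-value thresholding,
    dosage-weighted scoring), a hierarchical "factors of curves" latent
    growth structural equation model estimated by full-information maximum
    likelihood with missing data, regression-method factor scores, fit
    indices, variance decomposition, genetic association models for latent
    level, slope and lifetime cognitive change with FDR correction,
    mediation decomposition, per-score phenotype validation (partial and
    Nagelkerke R-squared), Horn's parallel analysis, and a synthetic cohort
    generator emulating a four-wave study of thirteen cognitive tests with
    monotone score-dependent dropout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges
Config/testthat/edition: 3
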