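Package: comorbidcv
Title: Classifier-Chain Ensembles and Permutation-Tested Cross-Validation
    for Comorbid Disorder Prediction
Version: 0.1.0
Authors@R:
    person("Richard", "Mayer", email = "rmayer@example.org",
           role = c("aut", "cre"))
Description: Evaluation machinery for multi-label prediction of comorbid
    psychiatric disorders from structural-neuroimaging features: derivation
    of binary diagnoses from multi-informant reports via the OR rule,
    linear confound residualization, gradient-boosted classifier-chain
    ensembles against a logistic baseline, repeated multi-label-stratified
    cross-validation with AUROC and Youden-index operating points, and
    permutation-based significance testing with Bonferroni correction.
    Includes a latent-liability synthetic-cohort generator so the full
    pipeline is testable without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
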