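Package: ofbn
Title: Bayesian Network Analysis of Oral Frailty Risk in Maintenance
    Hemodialysis Patients
Version: 0.1.0
Authors@R:
    person("Maintainer", "ofbn", email = "ofbn@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for studying oral-frailty risk in
    maintenance-hemodialysis cohorts: univariate screening (Pearson
    chi-square, t and Mann-Whitney tests), multivariable binary logistic
    regression fitted by iteratively reweighted least squares with Wald
    inference and collinearity diagnostics, discrete Bayesian-network
    structure learning by the Max-Min Hill-Climbing algorithm with expert
    edge constraints, maximum-likelihood parameter estimation, exact
    posterior inference by variable elimination, node-level sensitivity
    analysis, and model validation (ROC/AUC, Youden operating point,
    calibration, Hosmer-Lemeshow).  Ships a published 12-node reference
    network for oral frailty together with an ancestral sampler so the
    whole pipeline can be exercised on synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
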