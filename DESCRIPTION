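Package: centresim
Title: Centre-Adjustment Methods for Multicentre Trials with a Binary Outcome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation framework for comparing methods of accounting for
    centre-effects in multicentre randomised trials with a binary outcome.
    Provides a trial simulator with controllable intraclass correlation
    (latent-logistic outcome model with normal centre effects), stratified
    permuted-block and simple randomisation, five estimators (unadjusted
    logistic, fixed-effects logistic, random-effects logistic fitted by
    adaptive Gauss-Hermite quadrature, generalised estimating equations
    with model-based or sandwich standard errors, and Mantel-Haenszel with
    Robins-Breslow-Greenland variance), and a Monte-Carlo evaluation engine
    reporting mean treatment effect, type I error, power, and convergence
    rates over configurable scenario grids.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
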