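Package: sharederr
Title: Simulation and Correction of Shared Dose Measurement Error in
    Radiation Dose-Response Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Monte Carlo study engine for dose-measurement-error correction
    in radiation epidemiology.  Simulates nested ensembles of true and
    surrogate doses under a composite lognormal error model with shared and
    unshared Berkson and classical components, generates cancer case counts
    under linear and linear-quadratic excess relative risk models, and fits
    Poisson linear relative-risk models with profile-likelihood confidence
    intervals.  Implements five correction estimators (unadjusted
    regression, regression calibration, Monte Carlo maximum likelihood,
    quasi two-dimensional Monte Carlo with Bayesian model averaging, and
    AIC-weighted frequentist model averaging) together with an evaluation
    harness that measures coverage probability, mean coefficients,
    percentage bias, and bias in predicted excess relative risk across
    error scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    parallel,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
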