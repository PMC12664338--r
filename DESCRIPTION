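Package: actidsem
Title: Day-to-Day Dynamics of Physical Activity and Sedentary Behavior via
    Multilevel Dynamic Structural Equation Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying day-to-day coupling of accelerometer-measured
    sedentary behavior (SB) and physical activity (PA). Implements the standard
    hip-worn accelerometer preprocessing chain (epoch collapsing, non-wear
    detection with a low-count allowance, 100 counts-per-minute intensity
    classification, valid-day and valid-week protocols), and fits a Bayesian
    bivariate multilevel first-order vector-autoregressive dynamic structural
    equation model (DSEM) by Metropolis-within-Gibbs sampling. Person-specific
    means, autoregressive and cross-lagged slopes, and log innovation variances
    are random effects, optionally regressed on a person-level symptom
    predictor. Includes a synthetic-data generator with known ground truth,
    model-implied standardization, deviance information criterion, convergence
    diagnostics, and tidy/broom-style summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    jsonlite,
    readr,
    stats,
    utils,
    generics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
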