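Package: rdsem
Title: Bayesian Two-Level Residual Dynamic Structural Equation Models for
    Longitudinal Cohort Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits Bayesian two-level residual dynamic structural equation
    models (rDSEM) to unequally spaced longitudinal panel data: a latent-mean
    centred, detrended multivariate lag-1 autoregression on within-person
    residuals, with random person-level intercepts and linear time trends
    regressed on baseline covariates. Includes tools for panel validation,
    time-lattice expansion of unequal measurement schedules, missingness
    diagnostics, intraclass correlations, a calibrated synthetic-cohort
    generator with configurable attrition and item missingness, a blocked
    Gibbs sampler with data augmentation for missing and phantom occasions,
    convergence diagnostics (split-chain Rhat, effective sample size),
    STDYX standardization, and within/between R-squared reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
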