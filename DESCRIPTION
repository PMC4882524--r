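Package: foliarsem
Title: Structural Equation Models for Trait-Environment Determinants of Foliar Nitrogen
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood covariance-structure (structural equation)
    modelling for trait-environment analyses, built around the determinants of
    leaf nitrogen content (per mass and per area) in a temperate oak. Provides
    a line-oriented path-model grammar with two-indicator latent variables,
    RAM-form implied covariances, ML fitting from a correlation or covariance
    matrix with fit indices (chi-square, RMSEA, AGFI, CFI, AIC), standardized
    solutions with standard errors, direct/indirect/total effect decomposition,
    exact orthogonal-shock variance partitioning, AIC-guided backward model
    search, and model-based Gaussian simulators (including exact-moment
    samples) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
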