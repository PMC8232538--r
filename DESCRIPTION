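Package: sarlogit
Title: Bayesian Structured Additive Logistic Regression for Spatial
    Survey Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits Bayesian structured additive logistic regression models
    to hierarchical (DHS-style) survey data: dummy-coded fixed effects,
    penalized B-spline (second-order random walk) smooths of metrical
    covariates, an intrinsic conditional autoregressive (ICAR) spatial
    field over administrative regions, and household/community random
    effects, estimated by a blocked Gibbs sampler with Polya-Gamma
    augmentation.  Includes construction of composite knowledge-score
    outcomes from survey questionnaires, descriptive tabulation, a
    synthetic-data generator with known ground truth for validation,
    deviance information criterion (DIC) model comparison, posterior
    odds-ratio tables, credible-interval significance maps and smooth
    effect curves.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    splines,
    stats,
    utils,
    yaml,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rjags
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
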