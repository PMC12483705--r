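Package: remed
Title: Robust and Efficient Mediation Analysis via Huber M-Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Robust estimation and inference for the indirect effect in the
    simple mediation model. The three mediation equations are fitted by
    M-regression with the Huber, least-squares or least-absolute-deviation
    loss using an iteratively reweighted least-squares algorithm with MAD
    scale estimation and multiple starting points. The Huber tuning constant
    can be selected from the data by minimizing a nonparametric estimate of
    the asymptotic-variance factor over a grid. Inference on the indirect
    effect is available through a robust Sobel test, a Monte-Carlo
    distribution-of-the-product interval, and percentile and BCa case
    bootstrap intervals. A simulation harness compares mean squared error,
    type-I error and power of the least-squares, least-absolute-deviation
    and Huber estimators under normal, Laplace, contaminated-normal and
    Student-t error distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
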