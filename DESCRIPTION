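Package: gpgee
Title: Group-Penalized Generalized Estimating Equations for Structured
    Multichannel Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Marginal regression for clustered responses measured on a
    condition-by-channel grid, such as event-related potential (ERP)
    amplitudes recorded from multiple electrodes under multiple stimulus
    conditions. Fits generalized estimating equations with a
    Kronecker-structured (condition x channel) working correlation and
    performs group variable selection with a group SCAD penalty, solved by
    a minorization-maximization Newton-Raphson algorithm with BIC tuning of
    the penalty level. Includes a simulation harness that generates
    correlated Gaussian responses with separable error covariance and
    summarizes selection accuracy and estimation error across replicates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    generics,
    withr,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
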