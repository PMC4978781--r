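Package: irtlink
Title: Linking Item Response Model Parameters Across Calibrations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking item response theory (IRT) parameters estimated
    in separate calibrations of the three-parameter logistic (3PL) model.
    Separate calibrations identify the model through different restrictions on
    the ability distribution, so the same items and persons obtain different
    parameter values; the package provides the linear linking functions that
    reconcile them, numerical demonstrations of the identifiability trade-offs
    that make linking necessary, design-based identification of the linking
    parameters from common items or persons, per-item linking estimates with
    first-order delta-method standard errors, precision-weighted pooling, the
    classical mean/mean, mean/sigma, and Stocking-Lord estimators, a
    Bock-Aitkin marginal maximum likelihood EM calibration routine, and a
    simulator for common-item linking studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
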