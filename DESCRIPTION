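Package: phasereq
Title: Phase-Dependent Nutrient Requirement Estimation from Flock Production Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Estimates phase-dependent nutrient requirements of broiler
    breeder hens from flock-week production records. Fits a single-neuron
    hyperbolic-tangent dose-response model with Bayesian regularization
    (evidence framework) to nutrient-intake versus chick-output data,
    derives the intake achieving a target fraction (default 95 percent) of
    the asymptotic response in closed form, quantifies uncertainty by
    nonparametric case-resampling bootstrap, and compares requirements
    across production phases with bootstrap post-hoc tests and compact
    letter displays. Includes linear and quadratic benchmark regressions
    with confidence bands, notched-boxplot summaries, a synthetic
    flock-week data generator for validation studies, and an end-to-end
    pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
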