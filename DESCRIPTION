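Package: plannsim
Title: Simulation-Based Comparison of Partial Logistic Survival Neural Networks and Cox Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to generate synthetic clinical-trial survival data that mimic an
    osteosarcoma randomised trial (stratified binary prognostic factors,
    stratum-conditional age, log-normal accelerated failure time survival and
    Weibull censoring calibrated to target censoring rates), to fit partial
    logistic artificial neural networks (PLANN original and extended) on
    person-period expansions of the data alongside a Cox proportional hazards
    baseline, and to compare the methods with censoring-aware discrimination
    and calibration metrics (Harrell's C-index on linear and nonlinear
    prognostic indices, inverse-probability-of-censoring-weighted Brier score,
    integrated Brier score, and quartile-group miscalibration error) across
    Monte-Carlo censoring and sample-size scenarios.
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
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
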