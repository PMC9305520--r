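Package: hdps
Title: High-Dimensional Propensity Score Analysis, Diagnostics and Reporting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the high-dimensional propensity score (HDPS) procedure
    for proxy confounder adjustment in coded healthcare databases: declaration
    of data dimensions, pre-exposure feature generation with a prevalence
    filter, recurrence-based expansion into binary covariates, prioritisation
    by the Bross bias formula, propensity-score estimation by logistic
    regression, and treatment-effect estimation by inverse probability of
    treatment weighted Cox regression with robust standard errors. Ships a
    diagnostic toolkit (propensity-score overlap, covariate prevalence and
    balance summaries, Bross score distributions, near-instrument detection),
    sensitivity analyses over the number of selected covariates and over
    influential-covariate removal, a seven-item structured report, and a
    synthetic claims-data simulator with known confounding structure for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
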