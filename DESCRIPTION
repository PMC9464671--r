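Package: valsim
Title: Simulation-Based Internal and External Validation of Clinical
    Prediction Models
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Monte-Carlo comparison of internal validation (repeated
    stratified cross-validation, holdout splitting, Harrell's
    optimism-corrected bootstrap) against external validation of a
    fixed-form clinical prediction model.  Simulates stage-stratified
    diffuse large B-cell lymphoma (DLBCL) cohorts with log-normal PET
    metrics (SUVpeak, metabolic tumor volume, lesion dissemination) and
    binary clinical flags, generates two-year progression labels by
    thresholding a published logistic risk equation and injecting fixed
    misclassification fractions, and scores every validation approach by
    ROC AUC and calibration slope.  Scenario runners reproduce external
    test sets with shifted case mix, positivity cutoffs, label-noise
    rates and PET reconstruction (EARL2-style) perturbations.
License: MIT + file LICENSE
Encoding: UTF-8
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
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
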