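Package: stcsurv
Title: Unanchored Simulated Treatment Comparison for Survival Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-adjusted indirect treatment comparison of survival
    outcomes in unanchored settings via simulated treatment comparison (STC).
    Fits covariate-adjusted standard parametric and Royston-Parmar flexible
    parametric survival models to individual patient data for an index
    treatment, predicts survival at the aggregate baseline characteristics of
    comparator trials, and compares against comparator Kaplan-Meier data using
    restricted mean survival time differences and time-varying (landmark)
    hazard ratios with dual bootstrap uncertainty. Includes reconstruction of
    pseudo individual patient data from digitized Kaplan-Meier curves and
    numbers-at-risk tables, kernel-smoothed hazard estimation from
    Kaplan-Meier data, a two-stage AIC model-selection workflow, and a
    synthetic-data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    flexsurv,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
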