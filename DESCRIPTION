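Package: mirstress
Title: Cooperative-Game Ranking of Stress-Responsive miRNAs and
    Kernel-Regression Prediction of Plant Abiotic Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for biosensor-measured miRNA concentrations
    in Arabidopsis thaliana leaves under graded abiotic stress (drought,
    salinity, cold, heat). Ranks the contribution of each miRNA to stress
    discrimination with the normalized Banzhaf power index over feature
    coalitions, generates replicate-level and planted-signal synthetic
    datasets from printed summary statistics, and predicts stress type and
    level from selected miRNA concentrations with kernel regression models
    (epsilon-SVR, least-squares SVM, CART, Naive Bayes) evaluated by k-fold
    cross-validated R-squared.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
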