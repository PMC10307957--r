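Package: gazescreen
Title: Oculomotor Screening for Mild Cognitive Impairment from Saccade Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, scoring and statistical analysis of interleaved
    prosaccade/antisaccade and Go/No-go eye-tracking sessions for screening
    mild cognitive impairment (MCI). Generates synthetic 300 Hz gaze traces
    with known ground-truth trial outcomes, detects saccades and fixations
    with a velocity-threshold detector, classifies trials into correct,
    anticipation, omission and corrected/uncorrected inhibition-error
    categories, aggregates per-subject eye-movement metrics, estimates crude
    and covariate-adjusted odds ratios with Wald intervals, and runs a
    leakage-free classification benchmark (logistic regression, random
    forest, RBF support vector machine, gradient boosting) with SMOTE
    applied inside cross-validation folds, AUROC and binomial-deviance
    evaluation, and permutation feature importance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    glmnet,
    ranger,
    e1071,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr
Config/testthat/edition: 3
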