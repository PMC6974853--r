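Package: dynland
Title: Landmark Models for Dynamic Prediction of Survival
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Dynamic prediction of survival by landmarking. Builds the
    stacked landmark "super dataset" by truncation and administrative
    censoring, fits stratified and proportional-baselines landmark
    supermodels with smoothly landmark-varying coefficients via a Breslow
    partial-likelihood engine supporting delayed entry and cluster-robust
    covariances, predicts sliding-window death probabilities, and evaluates
    predictions dynamically with window-restricted concordance, IPCW Brier
    prediction-error curves against a Kaplan-Meier null, and time-dependent
    AUC. Includes a registry-style breast-cancer cohort simulator for
    testing the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    ggplot2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
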