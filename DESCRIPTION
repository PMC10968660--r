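Package: metaselect
Title: Metaheuristic Wrapper Feature Selection for Survey Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Wrapper feature selection for mixed-type survey data under class
    imbalance. Implements a binary-encoded genetic algorithm and a binary
    harmony search over feature masks, with linear dynamic parameter schedules
    (harmony memory consideration rate and mutation rate), a native naive
    Bayes classifier scored by stratified 5-fold cross-validation as the
    wrapper fitness, correlation-based (CFS) and information-gain filter
    baselines, imbalance-aware evaluation metrics (accuracy, support-weighted
    F1, AUC), a synthetic survey-data generator with known informative
    features, and an experiment runner with pluggable evaluation classifiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    foreign,
    jsonlite,
    rpart,
    ranger,
    e1071
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
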