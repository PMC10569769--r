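Package: navfair
Title: Prediction-Informed Fair Distribution of Patients Among Cancer
    Patient Navigators
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying fair workload allocation among cancer
    patient navigators (CPNs). Implements a weekly unfairness metric
    (mean absolute deviation of per-navigator workload from the
    specialty's equal share), a calibrated synthetic longitudinal cohort
    generator with zero-inflated encounter counts, EHR-style
    preprocessing rules (activity windows, Monday sampling, patient-level
    splits, workload-proxy evaluation), a two-stage workload predictor
    (k-prototypes clustering of mixed-type patient-weeks followed by
    tuned gradient-boosted regression), an exact minimum-unfairness
    assignment optimizer with a patient-stays-with-navigator consistency
    constraint, and a multi-week simulation harness comparing
    prediction-informed, random, and future-informed distribution
    policies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    nnet,
    optparse
Config/testthat/edition: 3
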