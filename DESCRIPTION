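Package: swayrisk
Title: Fall-Risk Classification from Trunk-Sway Posturography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for classifying fall risk in community-dwelling older
    adults from trunk-sway posturography. Extracts 31 stabilogram
    parameters (time-domain distance, area, hybrid, and frequency-domain
    measures) per stance condition from two-axis trunk-displacement
    trajectories, selects features with binary metaheuristic wrappers
    (Slime Mould Algorithm, Harris Hawks Optimization, Artificial Bee
    Colony) driven by a composite geometric-mean/AUC/sparsity fitness,
    fits imbalance-aware classifiers (Easy Ensemble, Balanced Bagging,
    Complement Naive Bayes) under two risk labels (fall history and
    Timed-Up-and-Go time), and explains fitted models with Shapley
    values. Includes a seeded synthetic-cohort generator so the full
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    rpart,
    nnet,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
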