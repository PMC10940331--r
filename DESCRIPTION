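Package: mycog
Title: Cognitive-Impairment Screening with Higher-Order IRT Scores and
    Machine-Learned Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores multi-instrument cognitive assessments with a
    higher-order two-parameter logistic item response theory model fitted
    by Markov chain Monte Carlo, builds classical and composite screening
    scores with a logistic link, searches mismatch-minimizing score cut
    points, and benchmarks classifiers (grid-search cross-validation and
    bootstrap evaluation) for predicting cognitive impairment. Includes a
    synthetic cohort generator matching the structure of an 86-patient
    primary-care screening study and that study's published per-patient
    score table as a packaged, checksummed fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    e1071,
    glmnet,
    rpart,
    class,
    randomForest,
    xgboost,
    nnet,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    pROC
Config/testthat/edition: 3
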