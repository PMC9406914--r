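Package: ebgwo
Title: Enhanced Binary Grey Wolf Optimization for Wrapper Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wrapper feature-subset selection for high-dimensional tabular
    biomarker data using an enhanced binary grey wolf optimizer (EBGWO):
    leader-guided encircling dynamics with a linearly decaying coefficient
    schedule, Levy-flight exploration steps generated by the Mantegna
    construction, a steep sigmoid transfer function for stochastic
    binarization, and a k-nearest-neighbour wrapper fitness combining
    validation error with a feature-count penalty. Includes readers for
    comma-separated vocal-feature tables in the UCI Parkinson's speech
    dialect, z-score standardization, seeded stratified train/test splits,
    a seeded synthetic cohort generator with planted class-informative
    columns, confusion-matrix and rank-based AUC metrics, downstream
    classifier evaluation (k-NN, RBF-SVM, decision tree, leaf-wise
    gradient-boosted trees), and an end-to-end experiment pipeline with a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    e1071,
    jsonlite,
    rpart,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
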