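Package: dasd
Title: Metaheuristic Filtering and Prototype-Reduced Weighted KNN for
    Blood-Biomarker Diagnosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-layer diagnostic pipeline for binary classification of
    blood-biomarker panels. A data-filter layer removes irrelevant features
    with a binary grey wolf optimization wrapper and rejects corrupted
    training rows with a binary genetic algorithm. A diagnostic layer fits an
    enhanced K-nearest-neighbor classifier that maps samples into a
    naive-Bayes weight space, compresses the training set into a small set of
    generated prototypes with the chimp optimization algorithm, and
    classifies by K-nearest-neighbor vote over the prototypes; an ensemble
    selector picks the best of several candidate classifiers by validation
    accuracy. Includes a synthetic biomarker-panel generator with planted
    informative features and outliers so every stage can be validated against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
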