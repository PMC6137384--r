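Package: rnncluster
Title: Random Neural Network Cluster for Functional Connectivity
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Random-subspace ensembles of neural network classifiers
    ("random neural network clusters") for two-group classification of
    functional-connectivity features derived from regional brain time
    series. Each base learner is trained on a random subject subset and a
    random feature subset; the ensemble predicts by majority vote.
    Accuracy-thresholded frequency counting over the base learners ranks
    connectivity edges by importance, a feature-count scan picks the
    optimal subset size, and selected edges are mapped to per-region
    weights exportable for brain-network visualization. Includes a
    synthetic cohort generator that plants group-dependent correlations
    on chosen edges so every pipeline stage can be exercised without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    nnet,
    glmnet,
    jsonlite,
    optparse,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
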