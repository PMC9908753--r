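Package: braindgcnn
Title: Brain Functional-Connectivity Network Classification with a Deep
    Graph Convolutional Neural Network
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds functional-connectivity brain networks from ROI-averaged
    resting-state time series (Pearson correlation, threshold binarization),
    quantifies cohort-level network connectivity via the Warshall transitive
    closure, and classifies subject graphs (e.g. major depressive disorder
    versus controls) with a deep graph convolutional neural network using
    SortPooling, a 1-D convolutional head and dropout, trained with binary
    cross-entropy and Adam. Includes confusion-matrix metrics, ROC/AUC,
    stratified holdout, k-fold and leave-one-site-out evaluation, and a
    multi-site synthetic cohort generator with a controlled group difference
    in correlation structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
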