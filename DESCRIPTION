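Package: thermonet
Title: Hand-Thermogram Classification with a Compact CNN, Quanvolutional
    Features, and Hybrid Machine Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the automated classification of rheumatoid arthritis
    from rainbow-palette hand thermograms. Provides a synthetic thermogram
    generator with class-dependent joint hot-spot intensity, reproducible
    stratified dataset splitting and elastic/brightness/zoom augmentation, a
    compact six-block convolutional network (RANet) with an exact per-layer
    parameter accountant and a built-in training engine, a four-qubit
    statevector simulator driving a quanvolutional image transform and its
    classical classifier head, a hybrid pipeline that feeds deep features
    through random-forest impurity-based selection into SVM, k-NN and
    gradient-boosting classifiers, and full confusion-matrix/ROC reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    e1071,
    class,
    randomForest,
    xgboost,
    withr,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
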