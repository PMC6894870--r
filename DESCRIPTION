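Package: aednns
Title: Reconstruction-Error Based Dual Deep Neural Networks for Disease Risk Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Risk prediction for tabular health-survey cohorts using
    reconstruction error (RE) from deep autoencoders. An autoencoder fitted
    on the whole training set yields an RE threshold that splits the data
    and routes new samples between two deep neural network classifiers,
    while a second autoencoder fitted on high-risk rows only supplies a
    per-sample RE appended as an extra classifier input. Includes a
    synthetic cohort generator parameterised from published per-class
    feature distributions, PCA reconstruction backends, a cross-validation
    and comparator harness with ROC/AUC and Hanley-McNeil inference, and
    leave-one-feature-out and recursive feature-elimination ranking. The
    minibatch Adamax network trainer is implemented in compiled code.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    e1071,
    rpart,
    randomForest,
    class,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    yaml,
    optparse
Config/testthat/edition: 3
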