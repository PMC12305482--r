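Package: dwolsml
Title: Doubly Robust Estimation of Optimal Adaptive Treatment Strategies
    with Machine-Learned Propensities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of optimal adaptive treatment strategies (dynamic
    treatment regimes) by dynamic weighted ordinary least squares (dWOLS),
    a doubly robust, stagewise weighted regression of linear blip functions.
    Treatment probabilities may be modelled by logistic regression or by
    machine-learning algorithms (random forest, naive Bayes, support vector
    machines, neural networks, and a SuperLearner stacking ensemble) fitted
    under K-fold cross-fitting to avoid overfitting bias.  Inference is
    provided through an adaptive m-out-of-n bootstrap with data-driven
    subsample-size selection and convergence-rate estimation, with the
    standard percentile bootstrap as a baseline.  Includes a synthetic
    two-stage scenario generator and a replication harness computing bias,
    standard deviation, RMSE, RMSE ratios, Monte Carlo errors, and
    confidence-interval coverage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    pracma,
    randomForest,
    e1071,
    nnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
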