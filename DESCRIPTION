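Package: learncurve
Title: Repeated Random-Sampling Evaluation of Learning Methods Across
    Training-Set Sizes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Robust and reproducible evaluation of supervised learning
    methods by repeated random sampling over a grid of training-set
    sizes. Provides learning-curve estimation with uncertainty
    quantification (mean, SEM, confidence intervals per size),
    leakage-safe supervised feature screening (empirical-Bayes
    moderated t and permutation tests applied inside each training
    split), unsupervised pre-filtering (missingness, threshold,
    variability rules), grid-search hyperparameter tuning with the
    one-standard-error rule, confidence-interval based best-model
    selection, performance-weighted aggregation of feature importance
    across all fitted models, and self-contained HTML reports. Base
    learners (penalized GLMs, random forests, linear SVM, gradient
    boosting, k-nearest neighbours) are delegated to established
    implementations behind a uniform adapter.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    parallel,
    jsonlite,
    data.table,
    tibble,
    ggplot2,
    glmnet,
    ranger,
    e1071,
    xgboost,
    class,
    caret,
    pROC
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
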