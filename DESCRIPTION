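Package: megml
Title: Machine-Learning Classification of MEG Functional Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A discovery framework for classifying clinical groups from
    magnetoencephalography (MEG) functional connectomes. Edge features are
    weighted phase lag index (wPLI) values over all region pairs of the
    AAL-90 parcellation, computed per canonical frequency band. The package
    provides per-edge univariate screening, unsupervised structure checks
    (two-way hierarchical clustering and PCA), a nested machine-learning
    pipeline (stratified train/test split, 10-fold cross-validation with
    recursive random-forest feature selection feeding an SVM, consensus
    feature lists, label-permutation significance testing, external ROC/AUC
    evaluation), and an independent PLS-DA verification arm with VIP
    scoring. A synthetic-data module generates connectome datasets with
    planted group differences, both directly on the edge scale and from
    coupled oscillatory time series reduced through the built-in wPLI
    estimator, so every stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    e1071,
    randomForest,
    signal,
    jsonlite,
    mclust
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
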