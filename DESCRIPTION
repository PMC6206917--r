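Package: kernelGS
Title: Double RBF-Kernel Weighted Clustering for Gene Selection
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Filter feature selection for gene-expression cancer
    classification. Genes are weighted by a kernel-induced dissimilarity
    between samples and their class centroids, using a convex mixture of
    two Gaussian (RBF) kernels with different bandwidths, and the weights
    minimise a regularised weighted-clustering objective under a simplex
    constraint via a closed-form update. Includes the original
    single-kernel schedule (KBCGS) and the double-kernel schedule (DKBCGS),
    an evaluation harness (stratified k-fold cross-validation with SVM and
    KNN classifiers, accuracy, sensitivity, specificity and ROC curves),
    a hyperparameter grid search, and a seeded synthetic expression-data
    generator with known informative-gene ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    kernlab,
    class
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
biocViews: GeneExpression, Classification, FeatureExtraction, Microarray
Config/testthat/edition: 3
RoxygenNote: 7.3.3
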