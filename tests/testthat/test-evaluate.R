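test_that("topGenes selects by weight with index tie-breaking", {
    w <- GeneWeights(c(0.5, 0.3, 0.2))
    expect_identical(topGenes(w, 2), c(1L, 2L))
    expect_identical(topGenes(w, 3), 1:3)
    u <- GeneWeights(rep(1 / 4, 4))
    expect_identical(topGenes(u, 2), c(1L, 2L))
    expect_error(topGenes(w, 0), "must lie in")
    expect_error(topGenes(w, 4), "must lie in")
})

test_that("confusion-derived metrics satisfy the defining identities", {
    conf <- matrix(c(4L, 2L, 1L, 3L), 2, 2,
                   dimnames = list(predicted = c("a", "b"),
                                   truth = c("a", "b")))
    # positive class "b": TP=3, FN=1, TN=4, FP=2
    mt <- kernelGS:::.metricsFromConfusion(conf, positive = "b")
    expect_equal(mt$acc, 0.7)
    expect_equal(mt$tpr, 0.75)
    expect_equal(mt$tnr, 2 / 3)

    # randomised confusions: identities hold exactly
    set.seed(31)
    for (i in 1:25) {
        cf <- matrix(sample(0:20, 4, replace = TRUE), 2, 2,
                     dimnames = dimnames(conf))
        if (sum(cf[, 2]) == 0 || sum(cf[, 1]) == 0) next
        m <- kernelGS:::.metricsFromConfusion(cf, "b")
        TP <- cf["b", "b"]; FN <- cf["a", "b"]
        TN <- cf["a", "a"]; FP <- cf["b", "a"]
        expect_identical(m$acc, (TP + TN) / sum(cf))
        expect_identical(m$tpr, TP / (TP + FN))
        expect_identical(m$tnr, TN / (FP + TN))
    }

    # macro-averaging over 3 classes agrees with per-class recomputation
    cf3 <- matrix(sample(1:9, 9), 3, 3,
                  dimnames = list(predicted = letters[1:3],
                                  truth = letters[1:3]))
    m3 <- kernelGS:::.metricsFromConfusion(cf3, "b")
    recs <- sapply(1:3, function(i) cf3[i, i] / sum(cf3[, i]))
    expect_equal(m3$tpr, mean(recs))
})

test_that("ROC curves behave at the extremes and match an independent oracle", {
    perfect <- rocCurve(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
    expect_equal(perfect$auc, 1)
    expect_equal(perfect$points[1, ], c(fpr = 0, tpr = 0))
    expect_equal(perfect$points[nrow(perfect$points), ],
                 c(fpr = 1, tpr = 1))
    expect_true(all(diff(perfect$points[, "fpr"]) >= 0))

    set.seed(32)
    scores <- rnorm(1000)
    labels <- rbinom(1000, 1, 0.4)
    null <- rocCurve(scores, labels)
    expect_lt(abs(null$auc - 0.5), 0.05)
    # sign reversal maps auc to 1 - auc
    expect_equal(rocCurve(-scores, labels)$auc, 1 - null$auc,
                 tolerance = 1e-12)
    skip_if_not_installed("pROC")
    oracle <- as.numeric(pROC::auc(pROC::roc(labels, scores,
                                             quiet = TRUE,
                                             direction = "<")))
    expect_equal(null$auc, oracle, tolerance = 1e-10)
    expect_error(rocCurve(scores, rep(1, 1000)), "both classes")
})

test_that("stratified folds balance classes and power the CV contract", {
    set.seed(33)
    lab <- factor(rep(c("A", "B", "C"), c(30, 18, 12)))
    fa <- kernelGS:::.stratifiedFolds(lab, 6, seed = 4)
    for (f in seq_len(fa$folds)) {
        inFold <- table(lab[fa$assign == f])
        expected <- table(lab) / fa$folds
        expect_true(all(abs(inFold - expected) <= 1))
        # every class present in every training fold
        expect_true(all(table(lab[fa$assign != f]) > 0))
    }
    expect_warning(kernelGS:::.stratifiedFolds(
        factor(rep(c("A", "B"), c(20, 3))), 10, 1), "reducing folds")
    expect_error(kernelGS:::.stratifiedFolds(
        factor(c("A", "A", "B")), 2, 1), "single sample")
})

test_that("cross-validation separates what is separable and is deterministic", {
    ds <- separableSet()
    rep1 <- crossValidate(ds, k = 5, classifier = "knn", folds = 5,
                          seed = 7)
    expect_equal(rep1@acc, 1)
    expect_equal(sum(rep1@confusion), 30)
    expect_equal(rep1@auc, 1)
    expect_identical(rep1@positiveClass, "pos")  # lexicographically 2nd

    rep2 <- crossValidate(ds, k = 5, classifier = "knn", folds = 5,
                          seed = 7)
    expect_identical(rep1@confusion, rep2@confusion)
    expect_identical(rep1@rocPoints, rep2@rocPoints)

    svm <- crossValidate(ds, k = 5, classifier = "svm", folds = 5,
                         seed = 7)
    expect_gte(svm@acc, 0.9)
    expect_false(is.na(svm@auc))

    # fixed external subset route
    fixed <- crossValidate(ds, classifier = "knn", folds = 5, seed = 7,
                           selection = "fixed", subset = 1:5)
    expect_equal(fixed@k, 5L)
    expect_gte(fixed@acc, 0.9)
})

test_that("the k sweep finds the planted subset size regime", {
    sim <- simulateExpression(SyntheticSpec(30, 60, 2, nInformative = 8,
                                            effectSize = 2, seed = 12))
    sw <- sweepK(sim$dataset, kRange = c(1, 4, 8, 16), classifier = "knn",
                 folds = 5, seed = 3)
    expect_identical(sw@kValues, c(1L, 4L, 8L, 16L))
    expect_true(all(sw@meanError >= 0 & sw@meanError <= 1))
    best <- sw@meanError[match(sw@bestK, sw@kValues)]
    expect_lte(best, sw@meanError[1])  # best k no worse than k = 1
    one <- sweepK(sim$dataset, kRange = 1, classifier = "knn", folds = 5,
                  seed = 3)
    expect_identical(one@bestK, 1L)
})

test_that("grid search degenerates correctly and returns the full table", {
    ds <- separableSet(n = 20, l = 10)
    single <- gridSearchKernel(ds, gamma1Grid = 1, gamma2Grid = 0.1,
                               cGrid = 0.5, kRange = c(2, 5),
                               classifier = "knn", folds = 5, seed = 2)
    expect_equal(single$best@gamma1, 1)
    expect_equal(nrow(single$table), 1L)

    # a (gamma, gamma, c) diagonal scores identically to c = 1 at gamma
    diag <- gridSearchKernel(ds, gamma1Grid = 1, gamma2Grid = 1,
                             cGrid = c(0.5, 1), kRange = c(2, 5),
                             classifier = "svm", folds = 5, seed = 2)
    expect_equal(diag$table$accuracy[1], diag$table$accuracy[2],
                 tolerance = 1e-12)
})
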