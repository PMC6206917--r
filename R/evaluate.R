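## Stratified cross-validated evaluation of gene subsets with KNN and
## SVM classifiers, confusion-matrix metrics, ROC curves, a sweep over
## the subset size and a kernel-hyperparameter grid search.

## Evaluate expr under a deterministic seed without disturbing the
## caller's RNG stream.
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    expr
}

## Deterministic sub-seed derivation from one master seed.
.subSeed <- function(seed, offset) {
    (as.numeric(seed) * 10007 + offset) %% 2147483647
}

#' Indices of the top-k genes by weight
#'
#' @param weights a [GeneWeights-class] or [GeneSelection-class].
#' @param k subset size, between 1 and the number of genes.
#' @return integer vector of k gene indices in rank order (descending
#'   weight, ties by gene index ascending); deterministic.
#' @examples
#' topGenes(GeneWeights(c(0.5, 0.3, 0.2)), 2)
#' @export
topGenes <- function(weights, k) {
    r <- geneRanking(weights)
    if (length(k) != 1L || is.na(k) || k < 1L || k > length(r))
        stop(sprintf("'k' must lie in [1, %d]", length(r)))
    r[seq_len(as.integer(k))]
}

## Stratified fold assignment: per class, shuffle then deal round-robin,
## so per-fold class proportions deviate from the global ones by at most
## one sample per class, and every class with >= 2 samples is present in
## every training fold.
.stratifiedFolds <- function(labels, folds, seed) {
    labels <- as.factor(labels)
    sizes <- table(labels)
    m <- min(sizes)
    if (m < 2L)
        stop("class '", names(sizes)[which.min(sizes)],
             "' has a single sample; cross-validation is impossible")
    if (m < folds) {
        warning(sprintf(
            "smallest class has %d samples; reducing folds from %d to %d",
            m, folds, m), call. = FALSE)
        folds <- m
    }
    assign <- integer(length(labels))
    .withSeed(seed, {
        for (cl in levels(labels)) {
            idx <- which(labels == cl)
            idx <- idx[sample.int(length(idx))]
            assign[idx] <- rep_len(seq_len(folds), length(idx))
        }
    })
    list(assign = assign, folds = folds)
}

## z-score fitted on the training samples, applied to both partitions
## (no test-fold information enters the normalisation).
.foldNormalize <- function(train, test) {
    mu <- colMeans(train)
    sigma <- apply(train, 2L, stats::sd)
    safe <- ifelse(sigma == 0, 1, sigma)
    ntr <- sweep(sweep(train, 2L, mu, "-"), 2L, safe, "/")
    nte <- sweep(sweep(test, 2L, mu, "-"), 2L, safe, "/")
    zv <- sigma == 0
    if (any(zv)) { ntr[, zv] <- 0; nte[, zv] <- 0 }
    list(train = ntr, test = nte)
}

## Double-RBF kernel on whole feature vectors, in the form kernlab
## expects for a user-supplied kernel.
.vectorKernel <- function(params) {
    f <- function(x, y) {
        d <- sum((x - y)^2)
        params@c * exp(-params@gamma1 * d) +
            (1 - params@c) * exp(-params@gamma2 * d)
    }
    class(f) <- "kernel"
    f
}

## Majority-vote KNN under the kernel-induced per-gene distance
## sum_k 2(1 - K(a_k, b_k)); returns labels and positive-vote fractions.
.kernelKnn <- function(train, test, cl, k, params, positive) {
    pred <- character(nrow(test))
    score <- numeric(nrow(test))
    for (i in seq_len(nrow(test))) {
        d <- colSums(2 * (1 - doubleRbfKernel(
            (t(train) - test[i, ])^2, params)))
        nb <- cl[order(d)[seq_len(k)]]
        tab <- table(nb)
        pred[i] <- names(tab)[which.max(tab)]
        score[i] <- mean(nb == positive)
    }
    list(pred = factor(pred, levels = levels(cl)), score = score)
}

.classify <- function(train, test, cl, classifier, params, knnK, svmCost,
                      knnDistance, positive) {
    if (classifier == "knn") {
        if (knnDistance == "kernel")
            return(.kernelKnn(train, test, cl, knnK, params, positive))
        pr <- class::knn(train, test, cl, k = knnK, prob = TRUE)
        p <- attr(pr, "prob")
        score <- ifelse(as.character(pr) == positive, p, 1 - p)
        list(pred = factor(as.character(pr), levels = levels(cl)),
             score = score)
    } else {
        fit <- kernlab::ksvm(train, cl, kernel = .vectorKernel(params),
                             C = svmCost, scaled = FALSE)
        pred <- kernlab::predict(fit, test)
        score <- rep(NA_real_, nrow(test))
        if (nlevels(cl) == 2L) {
            dec <- as.numeric(kernlab::predict(fit, test,
                                               type = "decision"))
            # orient the decision value towards the designated positive
            if (kernlab::lev(fit)[2L] == positive) score <- dec
            else score <- -dec
        }
        list(pred = factor(as.character(pred), levels = levels(cl)),
             score = score)
    }
}

.metricsFromConfusion <- function(conf, positive) {
    n <- sum(conf)
    acc <- sum(diag(conf)) / n
    cls <- colnames(conf)
    if (length(cls) == 2L) {
        neg <- setdiff(cls, positive)
        TP <- conf[positive, positive]; FN <- conf[neg, positive]
        TN <- conf[neg, neg]; FP <- conf[positive, neg]
        list(acc = acc, tpr = TP / (TP + FN), tnr = TN / (FP + TN))
    } else {
        rec <- spec <- numeric(length(cls))
        for (i in seq_along(cls)) {
            TPi <- conf[i, i]
            FNi <- sum(conf[-i, i])
            FPi <- sum(conf[i, -i])
            TNi <- n - TPi - FNi - FPi
            rec[i] <- TPi / (TPi + FNi)
            spec[i] <- TNi / (TNi + FPi)
        }
        list(acc = acc, tpr = mean(rec), tnr = mean(spec))
    }
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the unique score values (declaring
#' positive when the score is at or above the threshold), yielding one
#' (FPR, TPR) point per threshold, anchored at (0, 0) and (1, 1). The
#' area under the curve is computed by the trapezoid rule.
#'
#' @param scores numeric positive-class scores.
#' @param labels binary ground truth: logical, 0/1, or a two-level factor
#'   (second level = positive).
#' @return list with \code{points} (two-column fpr/tpr matrix) and
#'   \code{auc}.
#' @examples
#' rocCurve(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))$auc  # 1
#' @export
rocCurve <- function(scores, labels) {
    if (is.factor(labels)) {
        if (nlevels(labels) != 2L)
            stop("'labels' must be binary")
        labels <- labels == levels(labels)[2L]
    }
    labels <- as.logical(labels)
    if (length(scores) != length(labels))
        stop("'scores' and 'labels' must have equal length")
    if (all(labels) || !any(labels))
        stop("both classes must be present")
    P <- sum(labels); N <- sum(!labels)
    thr <- sort(unique(scores), decreasing = TRUE)
    tpr <- vapply(thr, function(t) sum(scores >= t & labels) / P,
                  numeric(1))
    fpr <- vapply(thr, function(t) sum(scores >= t & !labels) / N,
                  numeric(1))
    pts <- cbind(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
    pts <- unique(pts)
    o <- order(pts[, 1L], pts[, 2L])
    pts <- pts[o, , drop = FALSE]
    auc <- sum(diff(pts[, 1L]) *
               (pts[-1L, 2L] + pts[-nrow(pts), 2L]) / 2)
    list(points = pts, auc = auc)
}

#' Stratified cross-validated evaluation of a gene subset
#'
#' Splits the samples into stratified folds (deterministic given
#' \code{seed}), and for each fold normalises on the training samples,
#' picks the gene subset, trains the classifier and predicts the held-out
#' fold. Confusions are pooled over folds. By default the gene selection
#' is refit on each training fold (\code{selection = "fold"}), so no
#' test-fold information can leak into the ranking; \code{"global"}
#' reuses one ranking computed on all samples (the optimistic protocol),
#' and \code{"fixed"} evaluates an externally supplied subset, which is
#' how third-party rankings are compared.
#'
#' For two-class data, TPR/TNR are sensitivity and specificity of the
#' designated positive class (lexicographically second label unless
#' \code{positiveClass} is given) and a pooled ROC curve is computed from
#' the classifier scores. For multiclass data, TPR is the macro-averaged
#' per-class recall and TNR the macro-averaged per-class specificity.
#'
#' @param x a [GeneExpressionSet-class] (raw values; normalisation is
#'   fitted inside each training fold).
#' @param k number of top-ranked genes the classifier uses.
#' @param classifier \code{"knn"} (default: k = 5 nearest neighbours,
#'   Euclidean distance on the selected genes) or \code{"svm"} (maximum
#'   margin with the double-RBF kernel on the selected genes, cost
#'   \code{svmCost}).
#' @param folds number of folds (default 10; reduced with a warning when
#'   the smallest class is smaller).
#' @param seed integer seed fixing the fold assignment.
#' @param selection \code{"fold"}, \code{"global"} or \code{"fixed"}.
#' @param weights optional precomputed [GeneWeights-class] (used by
#'   \code{selection = "global"}; computed on all samples if missing).
#' @param subset integer gene indices for \code{selection = "fixed"}.
#' @param params [KernelParams-class] for selection and the SVM kernel.
#' @param variant,alpha,theta,maxIter optimiser settings, as in
#'   [selectGenes()].
#' @param knnK number of neighbours (default 5).
#' @param svmCost SVM cost parameter (default 1).
#' @param knnDistance \code{"euclidean"} (default) or \code{"kernel"}
#'   (the kernel-induced per-gene distance).
#' @param positiveClass label treated as positive in two-class metrics.
#' @return An [EvalReport-class].
#' @export
crossValidate <- function(x, k = 10L,
                          classifier = c("knn", "svm"), folds = 10L,
                          seed = 1L,
                          selection = c("fold", "global", "fixed"),
                          weights = NULL, subset = NULL,
                          params = KernelParams(),
                          variant = c("dkbcgs", "kbcgs"), alpha = 0.05,
                          theta = 1e-6, maxIter = 100L, knnK = 5L,
                          svmCost = 1,
                          knnDistance = c("euclidean", "kernel"),
                          positiveClass = NULL) {
    classifier <- match.arg(classifier)
    selection <- match.arg(selection)
    variant <- match.arg(variant)
    knnDistance <- match.arg(knnDistance)
    vals <- exprMatrix(x)
    lab <- classLabels(x)
    if (nlevels(lab) < 2L) stop("at least 2 classes are required")
    if (selection == "fixed") {
        if (is.null(subset) || length(subset) == 0L)
            stop("'subset' must be a non-empty index vector")
        k <- length(subset)
    }
    if (k < 1L || k > ncol(vals))
        stop(sprintf("'k' must lie in [1, %d]", ncol(vals)))
    if (selection == "global" && is.null(weights))
        weights <- selectGenes(x, params = params, variant = variant,
                               theta = theta, maxIter = maxIter,
                               alpha = alpha)@weights
    pos <- if (!is.null(positiveClass)) positiveClass
           else sort(levels(lab))[min(2L, nlevels(lab))]
    if (!pos %in% levels(lab)) stop("unknown positive class: ", pos)
    fa <- .stratifiedFolds(lab, folds, seed)
    levelsL <- levels(lab)
    emptyConf <- matrix(0L, nlevels(lab), nlevels(lab),
                        dimnames = list(predicted = levelsL,
                                        truth = levelsL))
    pooled <- emptyConf
    perFold <- vector("list", fa$folds)
    scores <- numeric(0); truth <- logical(0)
    for (f in seq_len(fa$folds)) {
        te <- fa$assign == f
        tr <- !te
        nm <- .foldNormalize(vals[tr, , drop = FALSE],
                             vals[te, , drop = FALSE])
        genes <- switch(selection,
            fold = {
                sel <- selectGenes(vals[tr, , drop = FALSE], lab[tr],
                                   params = params, variant = variant,
                                   theta = theta, maxIter = maxIter,
                                   alpha = alpha)
                topGenes(sel, k)
            },
            global = topGenes(weights, k),
            fixed = as.integer(subset))
        res <- .withSeed(.subSeed(seed, f), .classify(
            nm$train[, genes, drop = FALSE],
            nm$test[, genes, drop = FALSE],
            droplevels(lab[tr]), classifier, params,
            knnK, svmCost, knnDistance, pos))
        pred <- factor(as.character(res$pred), levels = levelsL)
        cf <- table(predicted = pred, truth = lab[te])
        conf <- emptyConf
        conf[rownames(cf), colnames(cf)] <- cf
        perFold[[f]] <- conf
        pooled <- pooled + conf
        if (nlevels(lab) == 2L && !anyNA(res$score)) {
            scores <- c(scores, res$score)
            truth <- c(truth, lab[te] == pos)
        }
    }
    mt <- .metricsFromConfusion(pooled, pos)
    roc <- if (nlevels(lab) == 2L && length(scores) &&
               any(truth) && !all(truth))
        rocCurve(scores, truth)
    else list(points = matrix(numeric(0), ncol = 2,
                              dimnames = list(NULL, c("fpr", "tpr"))),
              auc = NA_real_)
    new("EvalReport", confusion = pooled, acc = mt$acc, tpr = mt$tpr,
        tnr = mt$tnr, perFold = perFold, rocPoints = roc$points,
        auc = roc$auc, k = as.integer(k),
        classifierTag = sprintf("%s/%s-selection%s", classifier, selection,
                                if (classifier == "knn")
                                    sprintf(" (k=%d, %s)", knnK,
                                            knnDistance)
                                else sprintf(" (C=%g, double-RBF)",
                                             svmCost)),
        seed = as.integer(seed),
        positiveClass = as.character(pos))
}

#' Sweep the number of selected genes
#'
#' Runs [crossValidate()] for each subset size in \code{kRange} (same
#' fold assignment throughout, so the curves are comparable) and records
#' the mean error \code{1 - acc}. The best k is the smallest one
#' attaining the minimum error.
#'
#' @param x a [GeneExpressionSet-class].
#' @param kRange integer subset sizes (default 1:50).
#' @param ... passed to [crossValidate()] (classifier, folds, seed,
#'   selection, params, ...).
#' @return A [SweepResult-class].
#' @export
sweepK <- function(x, kRange = 1:50, ...) {
    kRange <- as.integer(kRange)
    if (any(kRange < 1L) || any(kRange > nrow(x)))
        stop("'kRange' must lie within 1..l")
    reports <- lapply(kRange, function(k) crossValidate(x, k = k, ...))
    err <- vapply(reports, function(r) 1 - r@acc, numeric(1))
    best <- kRange[which(err == min(err))]
    new("SweepResult", kValues = kRange, meanError = err,
        bestK = min(best), reports = reports)
}

#' Grid search over the kernel hyperparameters
#'
#' Full factorial evaluation of (gamma1, gamma2, c) triples; each triple
#' is scored by its best cross-validated accuracy over the k sweep. Ties
#' keep the first triple in iteration order (gamma1 outer, gamma2 middle,
#' c inner).
#'
#' @param x a [GeneExpressionSet-class].
#' @param gamma1Grid,gamma2Grid,cGrid candidate values.
#' @param kRange subset sizes scored for each triple (default 1:50).
#' @param ... passed to [crossValidate()].
#' @return list with \code{best} (a [KernelParams-class]) and
#'   \code{table} (one row per triple with its best k and accuracy).
#' @export
gridSearchKernel <- function(x, gamma1Grid, gamma2Grid, cGrid = 0.5,
                             kRange = 1:50, ...) {
    if (!length(gamma1Grid) || !length(gamma2Grid) || !length(cGrid))
        stop("grids must be non-empty")
    rows <- list()
    best <- NULL
    bestAcc <- -Inf
    for (g1 in gamma1Grid) for (g2 in gamma2Grid) for (cc in cGrid) {
        p <- KernelParams(gamma1 = g1, gamma2 = g2, c = cc)
        sw <- sweepK(x, kRange = kRange, params = p, ...)
        acc <- 1 - min(sw@meanError)
        rows[[length(rows) + 1L]] <- data.frame(
            gamma1 = g1, gamma2 = g2, c = cc, bestK = sw@bestK,
            accuracy = acc)
        if (acc > bestAcc) { bestAcc <- acc; best <- p }
    }
    list(best = best, table = do.call(rbind, rows))
}
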