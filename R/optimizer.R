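## The weighted-clustering gene selector. On z-scored data it computes
## class centroids, a per-gene kernel dissimilarity D (fixed across
## iterations), and alternates a closed-form simplex-constrained weight
## update with a rescaling of the regulariser delta until the objective
## J(w) = sum_k w_k D_k + delta * sum_k w_k^2 stabilises.

#' Class centroids of a labelled expression matrix
#'
#' Row i holds the gene-wise arithmetic mean of the samples in class i;
#' classes are ordered by first appearance in the labels.
#'
#' @param x normalised samples-by-genes matrix or
#'   [GeneExpressionSet-class].
#' @param labels class labels (ignored for a GeneExpressionSet).
#' @return A [ClusterCenters-class].
#' @export
computeCenters <- function(x, labels = NULL) {
    if (is(x, "GeneExpressionSet")) {
        labels <- classLabels(x)
        x <- exprMatrix(x)
    }
    labels <- factor(as.character(labels),
                     levels = unique(as.character(labels)))
    if (nlevels(labels) < 2L)
        stop("at least 2 classes are required")
    if (any(table(labels) == 0L))
        stop("every class must contain at least one sample")
    sizes <- as.integer(table(labels))
    centers <- rowsum(x, labels) / sizes
    centers <- as.matrix(centers)
    rownames(centers) <- levels(labels)
    new("ClusterCenters", centers = centers,
        classOrder = levels(labels), classSizes = sizes)
}

#' Per-gene kernel dissimilarity to the class centroids
#'
#' For gene k, sums the kernel-induced squared distance between every
#' sample's value and its own class centroid value:
#' \deqn{D_k = \sum_i \sum_{j \in C_i} \|\Phi(x_{jk}) - \Phi(v_{ik})\|^2.}
#' Each term lies in [0, 2), so \eqn{0 \le D_k < 2n}. D does not depend
#' on the gene weights and is computed once per selection run.
#'
#' @param x normalised samples-by-genes matrix or
#'   [GeneExpressionSet-class].
#' @param centers a [ClusterCenters-class]; computed if missing.
#' @param params a [KernelParams-class].
#' @param labels class labels (ignored for a GeneExpressionSet).
#' @return numeric vector of length l (named by gene when available).
#' @export
perGeneDissimilarity <- function(x, centers = NULL, params = KernelParams(),
                                 labels = NULL) {
    if (is(x, "GeneExpressionSet")) {
        labels <- classLabels(x)
        x <- exprMatrix(x)
    }
    labels <- factor(as.character(labels),
                     levels = unique(as.character(labels)))
    if (is.null(centers)) centers <- computeCenters(x, labels)
    if (!identical(centers@classOrder, levels(labels)))
        stop("'centers' classes do not match the labels")
    if (ncol(centers@centers) != ncol(x))
        stop(sprintf("centres have %d genes but the data has %d",
                     ncol(centers@centers), ncol(x)))
    v <- centers@centers[as.integer(labels), , drop = FALSE]
    colSums(kernelSqDistance(x, v, params))
}

## Euclidean projection of v onto the probability simplex
## (sort-based threshold algorithm).
.projectSimplex <- function(v) {
    u <- sort(v, decreasing = TRUE)
    css <- cumsum(u)
    rho <- max(which(u + (1 - css) / seq_along(u) > 0))
    tau <- (1 - css[rho]) / rho
    pmax(v + tau, 0)
}

#' Closed-form simplex-constrained weight update
#'
#' The stationary point of the Lagrangian of
#' \eqn{J(w) = \sum_k w_k D_k + \delta \sum_k w_k^2} under
#' \eqn{\sum_k w_k = 1} is
#' \deqn{w_k = \frac{1}{l} + \frac{1}{2\delta}\left(\bar D - D_k\right),}
#' with \eqn{\bar D} the mean dissimilarity; it sums to one algebraically.
#' When \eqn{\delta} is small this raw update can go negative, violating
#' \eqn{w_k \in [0, 1]}; negative entries are then clipped to zero and
#' the remaining mass renormalised by the simplex projection (a threshold
#' shift over the positive support), which restores the exact constrained
#' minimiser of J. Weights are non-increasing in \eqn{D_k}, so ranking by
#' weight equals ranking by ascending dissimilarity.
#'
#' @param D non-negative per-gene dissimilarity vector.
#' @param delta positive regularisation coefficient.
#' @return A [GeneWeights-class].
#' @examples
#' updateWeights(c(0, 2), delta = 1)  # weights (1, 0)
#' @export
updateWeights <- function(D, delta) {
    if (length(delta) != 1L || !is.finite(delta) || delta <= 0)
        stop("'delta' must be a single positive number")
    if (any(D < 0)) stop("'D' must be non-negative")
    l <- length(D)
    raw <- 1 / l + (mean(D) - D) / (2 * delta)
    w <- if (any(raw < 0)) .projectSimplex(raw) else raw
    stopifnot(any(w > 0))  # min-D gene's raw weight is >= 1/l for delta > 0
    GeneWeights(w / sum(w), geneIds = names(D))
}

#' Rescale the regulariser delta from the current weights
#'
#' Both schedules are built on the ratio of the weighted dissimilarity to
#' the squared weight norm,
#' \deqn{\delta = \left|\frac{\sum_k w_k D_k}{\sum_k w_k^2}\right|,}
#' which keeps the two terms of the objective on the same order of
#' magnitude. The double-kernel schedule (\code{"dkbcgs"}) uses the ratio
#' itself; the original single-kernel schedule (\code{"kbcgs"}) scales it
#' by a constant \code{alpha} (default 0.05). With uniform weights the
#' ratio equals \eqn{\sum_k D_k}.
#'
#' @param D non-negative per-gene dissimilarity vector.
#' @param w previous [GeneWeights-class] or numeric simplex vector.
#' @param variant \code{"dkbcgs"} (default) or \code{"kbcgs"}.
#' @param alpha scaling constant of the kbcgs schedule.
#' @return positive scalar delta.
#' @export
updateDelta <- function(D, w, variant = c("dkbcgs", "kbcgs"),
                        alpha = 0.05) {
    variant <- match.arg(variant)
    if (is(w, "GeneWeights")) w <- weightValues(w)
    if (any(D < 0)) stop("'D' must be non-negative")
    num <- sum(w * D)
    if (num == 0)
        stop("all weighted dissimilarities vanish; ",
             "data is perfectly class-separated per gene")
    ratio <- abs(num / sum(w^2))
    if (variant == "kbcgs") {
        if (length(alpha) != 1L || alpha <= 0)
            stop("'alpha' must be a single positive number")
        alpha * ratio
    } else ratio
}

#' Regularised weighted-clustering objective
#'
#' \deqn{J(w) = \sum_k w_k D_k + \delta \sum_k w_k^2.} On the simplex
#' \eqn{\sum_k w_k^2 \ge 1/l}, so \eqn{J \ge \delta / l}.
#'
#' @param D non-negative per-gene dissimilarity vector.
#' @param w a [GeneWeights-class] or numeric simplex vector.
#' @param delta positive regularisation coefficient.
#' @return scalar objective value.
#' @export
objectiveValue <- function(D, w, delta) {
    if (is(w, "GeneWeights")) w <- weightValues(w)
    sum(w * D) + delta * sum(w^2)
}

.runSelection <- function(values, labels, params, variant, theta, maxIter,
                          alpha) {
    l <- ncol(values)
    geneIds <- colnames(values)
    norm <- zscoreNormalize(values)
    centers <- computeCenters(norm$data, labels)
    D <- perGeneDissimilarity(norm$data, centers, params, labels)
    if (l == 1L) {
        st <- new("OptimizerState", t = 0L, delta = NA_real_,
                  objectiveTrace = numeric(), converged = TRUE,
                  theta = theta, maxIter = as.integer(maxIter),
                  alpha = alpha)
        return(new("GeneSelection", weights = GeneWeights(1, geneIds),
                   state = st, dissimilarity = D, centers = centers,
                   params = params, variant = variant))
    }
    w <- GeneWeights(rep(1 / l, l), geneIds)
    trace <- numeric()
    converged <- FALSE
    delta <- NA_real_
    t <- 0L
    degenerate <- FALSE
    while (t < maxIter) {
        delta <- tryCatch(
            updateDelta(D, w, variant = variant, alpha = alpha),
            error = function(e) {
                warning(conditionMessage(e), call. = FALSE)
                NA_real_
            })
        if (is.na(delta)) { degenerate <- TRUE; break }
        t <- t + 1L
        w <- updateWeights(D, delta)
        trace <- c(trace, objectiveValue(D, w, delta))
        if (t >= 2L && abs(trace[t] - trace[t - 1L]) < theta) {
            converged <- TRUE
            break
        }
    }
    st <- new("OptimizerState", t = t, delta = delta,
              objectiveTrace = trace, converged = converged && !degenerate,
              theta = theta, maxIter = as.integer(maxIter), alpha = alpha)
    new("GeneSelection", weights = w, state = st, dissimilarity = D,
        centers = centers, params = params, variant = variant)
}

#' @describeIn selectGenes run on a labelled expression container. The
#'   data are z-scored internally; the per-gene dissimilarity is computed
#'   once (it does not depend on the weights), the weights start uniform
#'   at 1/l, and each iteration first rescales delta from the previous
#'   weights and then applies the closed-form update, stopping when the
#'   absolute objective change drops below \code{theta} or after
#'   \code{maxIter} iterations.
#' @param params a [KernelParams-class].
#' @param variant delta schedule: \code{"dkbcgs"} (double kernel, default)
#'   or \code{"kbcgs"} (original, scaled by \code{alpha}).
#' @param theta convergence tolerance on the objective change
#'   (default 1e-6).
#' @param maxIter iteration cap (default 100).
#' @param alpha kbcgs scaling constant (default 0.05).
#' @export
setMethod("selectGenes", "GeneExpressionSet",
    function(x, params = KernelParams(), variant = c("dkbcgs", "kbcgs"),
             theta = 1e-6, maxIter = 100L, alpha = 0.05) {
        variant <- match.arg(variant)
        validObject(params)
        lab <- classLabels(x)
        if (nlevels(lab) < 2L)
            stop("at least 2 classes are required")
        .runSelection(exprMatrix(x), lab, params, variant, theta,
                      maxIter, alpha)
    })

#' @describeIn selectGenes run on a samples-by-genes matrix plus labels.
#' @param labels class labels, one per row of the matrix.
#' @export
setMethod("selectGenes", "matrix",
    function(x, labels, params = KernelParams(),
             variant = c("dkbcgs", "kbcgs"), theta = 1e-6, maxIter = 100L,
             alpha = 0.05) {
        selectGenes(GeneExpressionSet(x, labels = labels),
                    params = params, variant = match.arg(variant),
                    theta = theta, maxIter = maxIter, alpha = alpha)
    })
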