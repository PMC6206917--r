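#' @import methods
#' @importFrom stats sd rnorm predict
#' @importFrom utils read.delim write.table head
NULL

#' Parameters of the double RBF kernel
#'
#' The double RBF kernel is the convex mixture
#' \deqn{K(a, b) = c\,e^{-\gamma_1 (a-b)^2} + (1-c)\,e^{-\gamma_2 (a-b)^2}}
#' of two Gaussian kernels with bandwidth parameters \code{gamma1} and
#' \code{gamma2}. With \code{c = 1} (or \code{gamma1 == gamma2}) it reduces
#' to a single RBF kernel. A small second bandwidth gives the mixture a
#' heavier tail than either single kernel, so distant points retain a
#' non-negligible similarity.
#'
#' @slot gamma1 positive bandwidth of the first (typically local) kernel.
#' @slot gamma2 positive bandwidth of the second (typically flatter) kernel.
#' @slot c mixture coefficient in \code{[0, 1]}; weight of the first kernel.
#'
#' @seealso [doubleRbfKernel()], [kernelSqDistance()]
#' @export
setClass("KernelParams",
    representation(gamma1 = "numeric", gamma2 = "numeric", c = "numeric"),
    prototype(gamma1 = 1, gamma2 = 0.1, c = 0.5))

setValidity("KernelParams", function(object) {
    msg <- character()
    if (length(object@gamma1) != 1L || !is.finite(object@gamma1) ||
        object@gamma1 <= 0)
        msg <- c(msg, "'gamma1' must be a single positive number")
    if (length(object@gamma2) != 1L || !is.finite(object@gamma2) ||
        object@gamma2 <= 0)
        msg <- c(msg, "'gamma2' must be a single positive number")
    if (length(object@c) != 1L || !is.finite(object@c) ||
        object@c < 0 || object@c > 1)
        msg <- c(msg, "'c' must be a single number in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Construct kernel parameters
#'
#' @param gamma1 bandwidth of the first RBF component (default 1; on
#'   z-scored expression values, per-gene squared differences are O(1), so
#'   a unit bandwidth makes the first kernel sensitive at that scale).
#' @param gamma2 bandwidth of the second component (default 0.1, a flatter
#'   kernel supplying the heavy tail).
#' @param c mixture weight of the first component (default 0.5, the equal
#'   mixture).
#' @return A [KernelParams-class] object.
#' @examples
#' KernelParams(gamma1 = 1, gamma2 = 0.1, c = 0.5)
#' @export
KernelParams <- function(gamma1 = 1, gamma2 = 0.1, c = 0.5) {
    new("KernelParams", gamma1 = gamma1, gamma2 = gamma2, c = c)
}

setMethod("show", "KernelParams", function(object) {
    cat("Double RBF kernel parameters\n")
    cat(sprintf("  gamma1 = %g, gamma2 = %g, c = %g\n",
                object@gamma1, object@gamma2, object@c))
    if (object@c == 1 || object@c == 0 || object@gamma1 == object@gamma2)
        cat("  (degenerates to a single RBF kernel)\n")
})

#' Expression data with class labels
#'
#' A thin wrapper around [SummarizedExperiment::SummarizedExperiment] that
#' guarantees the structure the gene-selection machinery needs: one
#' \code{"exprs"} assay (genes in rows, samples in columns, no missing
#' values), unique gene and sample identifiers, and a \code{label} column
#' in \code{colData} with the class of every sample.
#'
#' The analysis formulation works with the transposed view (samples x
#' genes); [exprMatrix()] returns that orientation.
#'
#' @seealso [GeneExpressionSet()], [exprMatrix()], [classLabels()]
#' @export
setClass("GeneExpressionSet", contains = "SummarizedExperiment")

setValidity("GeneExpressionSet", function(object) {
    msg <- character()
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'exprs' is required")
    else {
        a <- SummarizedExperiment::assay(object, "exprs")
        if (!is.numeric(a))
            msg <- c(msg, "assay 'exprs' must be numeric")
        else if (anyNA(a))
            msg <- c(msg, "assay 'exprs' must not contain missing values")
    }
    if (!"label" %in% colnames(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData column 'label' is required")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "gene identifiers must be unique")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample identifiers must be unique")
    if (length(msg)) msg else TRUE
})

#' Construct a GeneExpressionSet
#'
#' @param values numeric matrix of expression values, samples in rows and
#'   genes in columns (the analysis orientation; it is stored transposed,
#'   following the genes-in-rows container convention).
#' @param labels class label per sample (length \code{nrow(values)});
#'   coerced to factor with levels in first-appearance order.
#' @param sampleIds,geneIds optional identifier vectors; default to the
#'   dimnames of \code{values} or generated \code{"S1..."}/\code{"g1..."}.
#' @return A [GeneExpressionSet-class].
#' @examples
#' x <- matrix(rnorm(12), nrow = 4)
#' ds <- GeneExpressionSet(x, labels = c("A", "A", "B", "B"))
#' ds
#' @export
GeneExpressionSet <- function(values, labels, sampleIds = NULL,
                              geneIds = NULL) {
    values <- as.matrix(values)
    if (!is.numeric(values))
        stop("'values' must be a numeric matrix")
    n <- nrow(values); l <- ncol(values)
    if (length(labels) != n)
        stop(sprintf("label/sample mismatch: %d samples vs %d labels",
                     n, length(labels)))
    if (is.null(sampleIds))
        sampleIds <- if (!is.null(rownames(values))) rownames(values)
                     else paste0("S", seq_len(n))
    if (is.null(geneIds))
        geneIds <- if (!is.null(colnames(values))) colnames(values)
                   else paste0("g", seq_len(l))
    if (anyDuplicated(geneIds)) {
        dup <- unique(geneIds[duplicated(geneIds)])
        stop("duplicate gene identifiers: ", paste(dup, collapse = ", "))
    }
    labels <- factor(as.character(labels),
                     levels = unique(as.character(labels)))
    a <- t(values)
    dimnames(a) <- list(geneIds, sampleIds)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = a),
        colData = S4Vectors::DataFrame(label = labels, row.names = sampleIds))
    new("GeneExpressionSet", se)
}

setMethod("show", "GeneExpressionSet", function(object) {
    lab <- classLabels(object)
    cat(sprintf("GeneExpressionSet: %d samples x %d genes\n",
                ncol(object), nrow(object)))
    cnt <- table(lab)
    cat(sprintf("  classes (%d): %s\n", nlevels(lab),
                paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", ")))
})

#' Per-gene normalisation record
#'
#' Stores the statistics of a z-score normalisation: per-gene mean and
#' (sample, n-1 denominator) standard deviation, and the indices of
#' zero-variance genes whose columns were set to zero.
#'
#' @slot mu per-gene means (length = number of genes).
#' @slot sigma per-gene sample standard deviations.
#' @slot zeroVarianceGenes integer indices of genes with sigma == 0.
#' @export
setClass("NormalizationRecord",
    representation(mu = "numeric", sigma = "numeric",
                   zeroVarianceGenes = "integer"))

setValidity("NormalizationRecord", function(object) {
    msg <- character()
    if (length(object@mu) != length(object@sigma))
        msg <- c(msg, "'mu' and 'sigma' must have equal length")
    if (any(object@sigma < 0))
        msg <- c(msg, "'sigma' must be non-negative")
    if (!identical(object@zeroVarianceGenes,
                   which(object@sigma == 0)))
        msg <- c(msg, "'zeroVarianceGenes' must be exactly which(sigma == 0)")
    if (length(msg)) msg else TRUE
})

setMethod("show", "NormalizationRecord", function(object) {
    cat(sprintf("NormalizationRecord for %d genes (%d zero-variance)\n",
                length(object@mu), length(object@zeroVarianceGenes)))
})

#' Simplex-constrained gene weights
#'
#' The weight vector produced by the optimiser: non-negative, summing to
#' one, together with the implied ranking (descending weight, ties broken
#' by gene index ascending).
#'
#' @slot weights named numeric vector on the probability simplex.
#' @slot ranking integer permutation; \code{ranking[r]} is the index of
#'   the gene at rank \code{r}.
#' @seealso [GeneWeights()], [topGenes()], [writeWeightTable()]
#' @export
setClass("GeneWeights",
    representation(weights = "numeric", ranking = "integer"))

setValidity("GeneWeights", function(object) {
    msg <- character()
    w <- object@weights
    if (length(w) == 0L)
        msg <- c(msg, "'weights' must be non-empty")
    if (any(w < 0) || any(w > 1))
        msg <- c(msg, "every weight must lie in [0, 1]")
    if (abs(sum(w) - 1) > 1e-10)
        msg <- c(msg, "weights must sum to 1 (within 1e-10)")
    if (!identical(object@ranking, order(-w, seq_along(w))))
        msg <- c(msg, "'ranking' must sort weights descending, ties by index")
    if (length(msg)) msg else TRUE
})

#' Construct a GeneWeights object
#'
#' @param weights numeric simplex vector (non-negative, sums to 1).
#' @param geneIds optional gene identifiers used as names.
#' @return A [GeneWeights-class]; the ranking is computed internally.
#' @examples
#' GeneWeights(c(0.5, 0.3, 0.2), geneIds = c("gA", "gB", "gC"))
#' @export
GeneWeights <- function(weights, geneIds = NULL) {
    weights <- as.numeric(weights)
    if (!is.null(geneIds)) {
        stopifnot(length(geneIds) == length(weights))
        names(weights) <- geneIds
    }
    new("GeneWeights", weights = weights,
        ranking = order(-weights, seq_along(weights)))
}

setMethod("show", "GeneWeights", function(object) {
    l <- length(object@weights)
    cat(sprintf("GeneWeights over %d genes\n", l))
    top <- object@ranking[seq_len(min(5L, l))]
    ids <- names(object@weights)
    if (is.null(ids)) ids <- paste0("g", seq_len(l))
    cat("  top:",
        paste(sprintf("%s=%.4g", ids[top], object@weights[top]),
              collapse = ", "), "\n")
})

#' State of the iterative weight optimiser
#'
#' @slot t number of completed iterations (0-based counter).
#' @slot delta final value of the regularisation coefficient.
#' @slot objectiveTrace objective value after each iteration.
#' @slot converged whether the absolute objective change fell below theta.
#' @slot theta convergence tolerance on |J(t+1) - J(t)| (default 1e-6).
#' @slot maxIter iteration cap (default 100).
#' @slot alpha scaling constant of the single-kernel (KBCGS) schedule.
#' @export
setClass("OptimizerState",
    representation(t = "integer", delta = "numeric",
                   objectiveTrace = "numeric", converged = "logical",
                   theta = "numeric", maxIter = "integer",
                   alpha = "numeric"))

setValidity("OptimizerState", function(object) {
    msg <- character()
    if (object@t > object@maxIter)
        msg <- c(msg, "'t' must not exceed 'maxIter'")
    if (length(msg)) msg else TRUE
})

setMethod("show", "OptimizerState", function(object) {
    cat(sprintf(
        "OptimizerState: %d iteration(s), %s (theta = %g), delta = %g\n",
        object@t,
        if (object@converged) "converged" else "not converged",
        object@theta, object@delta))
})

#' Class centroids of normalised expression data
#'
#' @slot centers C x l matrix; row i is the gene-wise mean of class i.
#' @slot classOrder class labels in first-appearance order.
#' @slot classSizes number of samples per class (sums to n).
#' @export
setClass("ClusterCenters",
    representation(centers = "matrix", classOrder = "character",
                   classSizes = "integer"))

setValidity("ClusterCenters", function(object) {
    msg <- character()
    if (nrow(object@centers) != length(object@classOrder))
        msg <- c(msg, "one centre row per class is required")
    if (length(object@classSizes) != length(object@classOrder))
        msg <- c(msg, "one class size per class is required")
    if (any(object@classSizes < 1L))
        msg <- c(msg, "every class must contain at least one sample")
    if (length(msg)) msg else TRUE
})

setMethod("show", "ClusterCenters", function(object) {
    cat(sprintf("ClusterCenters: %d classes x %d genes (%s)\n",
                nrow(object@centers), ncol(object@centers),
                paste(sprintf("%s=%d", object@classOrder,
                              object@classSizes), collapse = ", ")))
})

#' Result of a gene-selection run
#'
#' Bundles the final [GeneWeights-class], the [OptimizerState-class], the
#' per-gene dissimilarities D, the class centroids and the kernel
#' parameters used.
#'
#' @slot weights the final simplex-constrained weights.
#' @slot state the optimiser state (trace, convergence, delta).
#' @slot dissimilarity per-gene kernel dissimilarity vector D.
#' @slot centers class centroids on the normalised data.
#' @slot params kernel parameters used.
#' @slot variant \code{"dkbcgs"} or \code{"kbcgs"}.
#' @seealso [selectGenes()]
#' @export
setClass("GeneSelection",
    representation(weights = "GeneWeights", state = "OptimizerState",
                   dissimilarity = "numeric", centers = "ClusterCenters",
                   params = "KernelParams", variant = "character"))

setMethod("show", "GeneSelection", function(object) {
    cat(sprintf("GeneSelection (%s variant)\n", toupper(object@variant)))
    show(object@state)
    show(object@weights)
})

#' Cross-validated classification report
#'
#' @slot confusion pooled confusion matrix, predicted x truth.
#' @slot acc overall accuracy.
#' @slot tpr sensitivity TP/(TP+FN); macro-averaged recall if multiclass.
#' @slot tnr specificity TN/(FP+TN); macro-averaged if multiclass.
#' @slot perFold list of per-fold confusion matrices.
#' @slot rocPoints two-column (fpr, tpr) matrix; empty unless two-class.
#' @slot auc trapezoid area under the ROC curve (NA unless two-class).
#' @slot k number of genes used by the classifier.
#' @slot classifierTag classifier description string.
#' @slot seed RNG seed that fixed the fold assignment.
#' @slot positiveClass label treated as positive (two-class).
#' @export
setClass("EvalReport",
    representation(confusion = "matrix", acc = "numeric", tpr = "numeric",
                   tnr = "numeric", perFold = "list", rocPoints = "matrix",
                   auc = "numeric", k = "integer", classifierTag = "character",
                   seed = "integer", positiveClass = "character"))

setMethod("show", "EvalReport", function(object) {
    cat(sprintf("EvalReport [%s, k = %d genes, seed = %d]\n",
                object@classifierTag, object@k, object@seed))
    cat(sprintf("  ACC = %.4f, TPR = %.4f, TNR = %.4f", object@acc,
                object@tpr, object@tnr))
    if (!is.na(object@auc)) cat(sprintf(", AUC = %.4f", object@auc))
    cat("\n  pooled confusion (predicted x truth):\n")
    print(object@confusion)
})

#' Result of a sweep over the number of selected genes
#'
#' @slot kValues the subset sizes evaluated.
#' @slot meanError cross-validated mean error (1 - accuracy) per k.
#' @slot bestK smallest k attaining the minimum mean error.
#' @slot reports the per-k [EvalReport-class] objects.
#' @export
setClass("SweepResult",
    representation(kValues = "integer", meanError = "numeric",
                   bestK = "integer", reports = "list"))

setValidity("SweepResult", function(object) {
    msg <- character()
    if (length(object@kValues) != length(object@meanError))
        msg <- c(msg, "'kValues' and 'meanError' must have equal length")
    if (any(object@meanError < 0 | object@meanError > 1))
        msg <- c(msg, "'meanError' must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SweepResult", function(object) {
    cat(sprintf("SweepResult over k in [%d, %d]: best k = %d (error %.4f)\n",
                min(object@kValues), max(object@kValues), object@bestK,
                object@meanError[match(object@bestK, object@kValues)]))
})

#' Specification of a synthetic expression dataset
#'
#' Describes the generative model for seeded benchmark-like data: a noisy
#' background of uninformative genes plus a small set of informative genes
#' whose class means are shifted.
#'
#' @slot nSamples number of samples (>= 4).
#' @slot nGenes number of genes (>= 2).
#' @slot nClasses number of classes (>= 2).
#' @slot classProportions simplex vector of expected class shares.
#' @slot nInformative number of genes carrying class-dependent means.
#' @slot effectSize between-class shift in units of the noise SD.
#' @slot noiseSd within-class measurement noise SD (> 0).
#' @slot baselineSd SD of gene-specific baselines (>= 0).
#' @slot seed integer RNG seed; the dataset is a pure function of the spec.
#' @seealso [SyntheticSpec()], [simulateExpression()], [syntheticPresets()]
#' @export
setClass("SyntheticSpec",
    representation(nSamples = "integer", nGenes = "integer",
                   nClasses = "integer", classProportions = "numeric",
                   nInformative = "integer", effectSize = "numeric",
                   noiseSd = "numeric", baselineSd = "numeric",
                   seed = "integer"))

setValidity("SyntheticSpec", function(object) {
    msg <- character()
    if (object@nSamples < 4L) msg <- c(msg, "'nSamples' must be >= 4")
    if (object@nGenes < 2L) msg <- c(msg, "'nGenes' must be >= 2")
    if (object@nClasses < 2L) msg <- c(msg, "'nClasses' must be >= 2")
    if (length(object@classProportions) != object@nClasses ||
        any(object@classProportions <= 0) ||
        abs(sum(object@classProportions) - 1) > 1e-8)
        msg <- c(msg, "'classProportions' must be a positive simplex vector of length nClasses")
    if (object@nInformative < 0L || object@nInformative > object@nGenes)
        msg <- c(msg, "'nInformative' must lie in [0, nGenes]")
    if (object@effectSize < 0) msg <- c(msg, "'effectSize' must be >= 0")
    if (object@noiseSd <= 0) msg <- c(msg, "'noiseSd' must be > 0")
    if (object@baselineSd < 0) msg <- c(msg, "'baselineSd' must be >= 0")
    if (object@nSamples < object@nClasses)
        msg <- c(msg, "need at least one sample per class")
    if (length(msg)) msg else TRUE
})

#' Construct a synthetic-data specification
#'
#' @param nSamples,nGenes,nClasses dataset dimensions.
#' @param classProportions expected class shares (default balanced).
#' @param nInformative number of class-informative genes (default 20).
#' @param effectSize between-class mean shift in noise-SD units
#'   (default 2).
#' @param noiseSd measurement-noise SD (default 1).
#' @param baselineSd SD of per-gene baselines (default 1; removed again by
#'   z-scoring but realistic for raw intensities).
#' @param seed RNG seed (default 1).
#' @return A [SyntheticSpec-class].
#' @examples
#' SyntheticSpec(nSamples = 40, nGenes = 100, nClasses = 2, seed = 7)
#' @export
SyntheticSpec <- function(nSamples, nGenes, nClasses = 2L,
                          classProportions = rep(1 / nClasses, nClasses),
                          nInformative = 20L, effectSize = 2,
                          noiseSd = 1, baselineSd = 1, seed = 1L) {
    new("SyntheticSpec", nSamples = as.integer(nSamples),
        nGenes = as.integer(nGenes), nClasses = as.integer(nClasses),
        classProportions = as.numeric(classProportions),
        nInformative = as.integer(nInformative),
        effectSize = as.numeric(effectSize), noiseSd = as.numeric(noiseSd),
        baselineSd = as.numeric(baselineSd), seed = as.integer(seed))
}

setMethod("show", "SyntheticSpec", function(object) {
    cat(sprintf(
        "SyntheticSpec: n = %d, l = %d, C = %d, %d informative (effect %g sd), seed %d\n",
        object@nSamples, object@nGenes, object@nClasses,
        object@nInformative, object@effectSize, object@seed))
})
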