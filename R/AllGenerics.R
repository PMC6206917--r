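#' Expression values in the analysis orientation
#'
#' @param x a [GeneExpressionSet-class].
#' @return numeric matrix, samples in rows and genes in columns.
#' @export
setGeneric("exprMatrix", function(x) standardGeneric("exprMatrix"))

#' Class labels of the samples
#'
#' @param x a [GeneExpressionSet-class].
#' @return factor of length \code{n} with levels in first-appearance order.
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' Numeric weight vector
#'
#' @param x a [GeneWeights-class] or [GeneSelection-class].
#' @return named numeric vector on the simplex.
#' @export
setGeneric("weightValues", function(x) standardGeneric("weightValues"))

#' Gene ranking implied by the weights
#'
#' @param x a [GeneWeights-class] or [GeneSelection-class].
#' @return integer vector; element r is the gene index at rank r.
#' @export
setGeneric("geneRanking", function(x) standardGeneric("geneRanking"))

#' Run the kernel-weighted gene-selection optimiser
#'
#' @param x a [GeneExpressionSet-class], or a samples-by-genes numeric
#'   matrix (then \code{labels} is required).
#' @param ... passed on to methods; see the GeneExpressionSet method.
#' @return A [GeneSelection-class].
#' @seealso [GeneSelection-class] for the result container.
#' @export
setGeneric("selectGenes", function(x, ...) standardGeneric("selectGenes"))

#' @rdname exprMatrix
#' @export
setMethod("exprMatrix", "GeneExpressionSet", function(x) {
    t(SummarizedExperiment::assay(x, "exprs"))
})

#' @rdname classLabels
#' @export
setMethod("classLabels", "GeneExpressionSet", function(x) {
    lab <- SummarizedExperiment::colData(x)$label
    if (!is.factor(lab))
        lab <- factor(as.character(lab), levels = unique(as.character(lab)))
    lab
})

#' @rdname weightValues
#' @export
setMethod("weightValues", "GeneWeights", function(x) x@weights)

#' @rdname weightValues
#' @export
setMethod("weightValues", "GeneSelection", function(x) x@weights@weights)

#' @rdname geneRanking
#' @export
setMethod("geneRanking", "GeneWeights", function(x) x@ranking)

#' @rdname geneRanking
#' @export
setMethod("geneRanking", "GeneSelection", function(x) x@weights@ranking)
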