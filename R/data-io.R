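## Delimited-text I/O for expression matrices, labels and weight tables.
## Comma vs tab is auto-detected from the file extension (.csv => comma),
## overridable through `sep`.

.guessSep <- function(path, sep = NULL) {
    if (!is.null(sep)) return(sep)
    if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a delimited expression matrix and its labels
#'
#' The expected layout is a header row of gene identifiers and one row per
#' sample, with sample identifiers in the first column. Files with genes
#' in rows are read with \code{orientation = "genes"}, which transposes on
#' load.
#'
#' @param path path to the matrix file (CSV or TSV, by extension).
#' @param labels either a vector of length n, or the path of a label file:
#'   a single column of labels, or a two-column (sample_id, label) table
#'   with a header. Required for selection/evaluation, optional here.
#' @param orientation \code{"samples"} (rows are samples, the default) or
#'   \code{"genes"} (rows are genes; transposed on load).
#' @param sep field separator; default inferred from the extension.
#' @param impute \code{"none"} (reject missing values, the default) or
#'   \code{"mean"} (replace by the per-gene mean).
#' @return A [GeneExpressionSet-class] when labels are given, otherwise a
#'   list with \code{values}, \code{sampleIds}, \code{geneIds}.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("id,g1,g2", "s1,1,4", "s2,2,5", "s3,3,6"), tf)
#' ds <- readExpressionMatrix(tf, labels = c("A", "A", "B"))
#' exprMatrix(ds)
#' @export
readExpressionMatrix <- function(path, labels = NULL,
                                 orientation = c("samples", "genes"),
                                 sep = NULL, impute = c("none", "mean")) {
    orientation <- match.arg(orientation)
    impute <- match.arg(impute)
    sep <- .guessSep(path, sep)
    raw <- utils::read.delim(path, sep = sep, header = TRUE,
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(raw) < 2L)
        stop("matrix file must have an identifier column plus data columns")
    rowIds <- as.character(raw[[1L]])
    vals <- raw[, -1L, drop = FALSE]
    for (j in seq_along(vals)) {
        v <- vals[[j]]
        if (!is.numeric(v)) {
            suppressWarnings(num <- as.numeric(v))
            bad <- which(is.na(num) & !is.na(v) &
                         !toupper(trimws(v)) %in% c("NA", ""))
            if (length(bad))
                stop(sprintf(
                    "non-numeric value '%s' at row %d, column '%s'",
                    v[bad[1L]], bad[1L], colnames(vals)[j]))
            vals[[j]] <- num
        }
    }
    m <- as.matrix(vals)
    if (orientation == "genes") {
        values <- t(m)
        geneIds <- rowIds
        sampleIds <- colnames(m)
    } else {
        values <- m
        sampleIds <- rowIds
        geneIds <- colnames(m)
    }
    if (anyNA(values)) {
        if (impute == "none") {
            bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
            stop(sprintf(
                "missing value at sample %d, gene %d (set impute = \"mean\" to impute)",
                bad[1L], bad[2L]))
        }
        for (j in seq_len(ncol(values))) {
            nas <- is.na(values[, j])
            if (any(nas))
                values[nas, j] <- mean(values[, j], na.rm = TRUE)
        }
    }
    dimnames(values) <- list(sampleIds, geneIds)
    if (is.null(labels))
        return(list(values = values, sampleIds = sampleIds,
                    geneIds = geneIds))
    if (is.character(labels) && length(labels) == 1L && file.exists(labels))
        labels <- readLabels(labels, sampleIds = sampleIds)
    if (length(labels) != nrow(values))
        stop(sprintf("%d samples vs %d labels", nrow(values),
                     length(labels)))
    GeneExpressionSet(values, labels = labels, sampleIds = sampleIds,
                      geneIds = geneIds)
}

#' Read a label file
#'
#' Accepts a headerless single column of labels, or a delimited two-column
#' table (sample_id, label) with a header; in the latter case labels are
#' reordered to match \code{sampleIds} when given.
#'
#' @param path label file path.
#' @param sampleIds optional sample identifiers for order matching.
#' @param sep field separator; default inferred from the extension.
#' @return character vector of labels.
#' @export
readLabels <- function(path, sampleIds = NULL, sep = NULL) {
    sep <- .guessSep(path, sep)
    first <- readLines(path, n = 1L)
    twoCol <- length(strsplit(first, sep, fixed = TRUE)[[1L]]) >= 2L
    if (twoCol) {
        tab <- utils::read.delim(path, sep = sep, header = TRUE,
                                 stringsAsFactors = FALSE)
        lab <- as.character(tab[[2L]])
        ids <- as.character(tab[[1L]])
        if (!is.null(sampleIds)) {
            idx <- match(sampleIds, ids)
            if (anyNA(idx))
                stop("label file is missing samples: ",
                     paste(sampleIds[is.na(idx)], collapse = ", "))
            lab <- lab[idx]
        }
        lab
    } else {
        trimws(readLines(path))
    }
}

#' Write an expression matrix with labels
#'
#' Inverse of [readExpressionMatrix()]: header row of gene identifiers,
#' sample identifiers in the first column, one sample per row; labels go
#' to a companion two-column file when \code{labelPath} is given.
#'
#' @param ds a [GeneExpressionSet-class].
#' @param path output matrix path (.csv or .tsv).
#' @param labelPath optional output path for a (sample_id, label) table.
#' @param sep field separator; default inferred from the extension.
#' @return invisibly, \code{path}.
#' @export
writeExpressionMatrix <- function(ds, path, labelPath = NULL, sep = NULL) {
    sep <- .guessSep(path, sep)
    m <- exprMatrix(ds)
    df <- data.frame(id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE,
                       row.names = FALSE)
    if (!is.null(labelPath)) {
        ldf <- data.frame(sample_id = rownames(m),
                          label = as.character(classLabels(ds)))
        utils::write.table(ldf, labelPath, sep = .guessSep(labelPath, NULL),
                           quote = FALSE, row.names = FALSE)
    }
    invisible(path)
}

#' Write a ranked gene-weight table
#'
#' Tab-separated columns \code{rank}, \code{gene_id}, \code{weight},
#' sorted by rank (descending weight, ties by gene index). Weights are
#' printed with 12 significant digits so a round-trip reproduces them at
#' that precision.
#'
#' @param weights a [GeneWeights-class].
#' @param path output path.
#' @param geneIds optional identifiers overriding the names stored in
#'   \code{weights}.
#' @return invisibly, \code{path}.
#' @seealso [readWeightTable()]
#' @export
writeWeightTable <- function(weights, path, geneIds = NULL) {
    w <- weightValues(weights)
    if (is.null(geneIds)) geneIds <- names(w)
    if (is.null(geneIds)) geneIds <- paste0("g", seq_along(w))
    if (length(geneIds) != length(w))
        stop(sprintf("%d weights vs %d gene identifiers", length(w),
                     length(geneIds)))
    r <- geneRanking(weights)
    df <- data.frame(rank = seq_along(r), gene_id = geneIds[r],
                     weight = sprintf("%.12g", w[r]),
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a gene-weight table
#'
#' @param path a table written by [writeWeightTable()] (or any ranking
#'   table with gene_id and a numeric score column).
#' @return A [GeneWeights-class] in the table's gene order. Scores that do
#'   not sum to one (external rankings) are renormalised; negative scores
#'   are rejected.
#' @export
readWeightTable <- function(path) {
    tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
    wcol <- if ("weight" %in% colnames(tab)) "weight" else colnames(tab)[ncol(tab)]
    idcol <- if ("gene_id" %in% colnames(tab)) "gene_id" else colnames(tab)[1L]
    w <- as.numeric(tab[[wcol]])
    if (any(w < 0)) stop("weights must be non-negative")
    s <- sum(w)
    if (s <= 0) stop("weights must not be all zero")
    GeneWeights(w / s, geneIds = as.character(tab[[idcol]]))
}

#' Z-score normalise an expression matrix gene-wise
#'
#' Each gene column is replaced by \eqn{(x - \mu)/\sigma} where \eqn{\mu}
#' and \eqn{\sigma} are that gene's mean and sample standard deviation
#' (n-1 denominator) across all samples. Genes with zero variance are set
#' to all zeros and recorded.
#'
#' @param x a [GeneExpressionSet-class] or a samples-by-genes matrix.
#' @return list with \code{data} (same type as the input, normalised) and
#'   \code{record} (a [NormalizationRecord-class]).
#' @examples
#' zscoreNormalize(cbind(g1 = c(1, 2, 3)))$data
#' @export
zscoreNormalize <- function(x) {
    isSet <- is(x, "GeneExpressionSet")
    m <- if (isSet) exprMatrix(x) else as.matrix(x)
    if (nrow(m) < 2L)
        stop("at least 2 samples are required (standard deviation undefined)")
    mu <- colMeans(m)
    sigma <- apply(m, 2L, stats::sd)
    zv <- which(sigma == 0)
    z <- sweep(m, 2L, mu, "-")
    safe <- ifelse(sigma == 0, 1, sigma)
    z <- sweep(z, 2L, safe, "/")
    if (length(zv)) z[, zv] <- 0
    rec <- new("NormalizationRecord", mu = unname(mu),
               sigma = unname(sigma), zeroVarianceGenes = unname(zv))
    out <- if (isSet)
        GeneExpressionSet(z, labels = classLabels(x),
                          sampleIds = rownames(m), geneIds = colnames(m))
    else z
    list(data = out, record = rec)
}
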