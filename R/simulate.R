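## Seeded synthetic expression data with known informative-gene ground
## truth, shaped like small-n / large-l microarray benchmarks.

#' Generate a synthetic expression dataset
#'
#' Gene g gets a baseline \eqn{b_g \sim N(0, baselineSd^2)}. The first
#' \code{nInformative} genes additionally carry a class-dependent mean
#' shift \eqn{\mu_{g,i} = effectSize \cdot noiseSd \cdot s_i} with the
#' class scores \eqn{s_i} equally spaced in [-1, 1] (so two classes sit
#' at -1 and +1, and multiclass problems have ordered symmetric
#' structure). Every measurement adds \eqn{N(0, noiseSd^2)} noise. The
#' dataset is a pure function of the spec (including its seed).
#'
#' @param spec a [SyntheticSpec-class].
#' @return list with \code{dataset} (a [GeneExpressionSet-class]) and
#'   \code{informative} (integer indices of the informative genes).
#' @examples
#' sim <- simulateExpression(SyntheticSpec(40, 100, nInformative = 5))
#' sim$informative
#' @export
simulateExpression <- function(spec) {
    validObject(spec)
    n <- spec@nSamples; l <- spec@nGenes; C <- spec@nClasses
    # largest-remainder rounding of the class counts, each class >= 1
    raw <- spec@classProportions * n
    counts <- pmax(1L, floor(raw))
    while (sum(counts) < n) {
        i <- which.max(raw - counts)
        counts[i] <- counts[i] + 1L
    }
    while (sum(counts) > n) {
        i <- which.max(counts - raw)
        counts[i] <- counts[i] - 1L
    }
    classes <- paste0("class", seq_len(C))
    labels <- rep(classes, counts)
    spacing <- if (C == 1L) 0 else seq(-1, 1, length.out = C)
    informative <- seq_len(spec@nInformative)
    .withSeed(spec@seed, {
        baseline <- stats::rnorm(l, 0, spec@baselineSd)
        shift <- matrix(0, C, l)
        if (spec@nInformative > 0L)
            shift[, informative] <- spec@effectSize * spec@noiseSd * spacing
        classIdx <- rep(seq_len(C), counts)
        values <- matrix(stats::rnorm(n * l, 0, spec@noiseSd), n, l)
        values <- values + shift[classIdx, , drop = FALSE]
        values <- sweep(values, 2L, baseline, "+")
    })
    dimnames(values) <- list(paste0("S", seq_len(n)),
                             paste0("g", seq_len(l)))
    list(dataset = GeneExpressionSet(values, labels = labels),
         informative = as.integer(informative))
}

#' Benchmark-shaped synthetic presets
#'
#' Named [SyntheticSpec-class] objects matching the (samples, classes,
#' genes) shape of four widely used expression benchmarks, with 20
#' informative genes, effect size 2 and unit noise by default.
#'
#' @param seed seed stored in every preset (default 1).
#' @return named list of [SyntheticSpec-class] objects:
#'   \code{"dlbcl-like"} (77 x 7129, 2 classes), \code{"gastric-like"}
#'   (40 x 1519, 2 classes), \code{"lymphoma-like"} (62 x 4026, 3
#'   classes) and \code{"multicancer-like"} (152 x 65522, 5 classes).
#' @examples
#' syntheticPresets()[["gastric-like"]]
#' @export
syntheticPresets <- function(seed = 1L) {
    list(
        "dlbcl-like" = SyntheticSpec(77L, 7129L, 2L, seed = seed),
        "gastric-like" = SyntheticSpec(40L, 1519L, 2L, seed = seed),
        "lymphoma-like" = SyntheticSpec(62L, 4026L, 3L, seed = seed),
        "multicancer-like" = SyntheticSpec(152L, 65522L, 5L, seed = seed))
}
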