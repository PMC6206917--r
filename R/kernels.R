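## RBF kernels on pre-squared distances. The gene-weighting machinery
## applies kernels coordinate-wise (one gene value at a time), so these
## functions take the squared difference directly; callers never pass an
## unsquared distance.

.checkSqDist <- function(sqDist) {
    if (any(sqDist < 0))
        stop("'sqDist' must be non-negative (it is a squared distance)")
}

#' Single RBF (Gaussian) kernel on a squared distance
#'
#' \deqn{K(d) = e^{-\gamma d}} where \eqn{d = \|a - b\|^2} is already
#' squared. Equals 1 iff \eqn{d = 0}, strictly decreasing in \eqn{d},
#' bounded in (0, 1].
#'
#' @param sqDist non-negative squared distance(s); vectorised.
#' @param gamma positive bandwidth.
#' @return kernel value(s) in (0, 1].
#' @examples
#' rbfKernel(1, gamma = 1)  # exp(-1)
#' @export
rbfKernel <- function(sqDist, gamma) {
    if (length(gamma) != 1L || !is.finite(gamma) || gamma <= 0)
        stop("'gamma' must be a single positive number")
    .checkSqDist(sqDist)
    exp(-gamma * sqDist)
}

#' Double RBF kernel on a squared distance
#'
#' The convex mixture \eqn{c\,e^{-\gamma_1 d} + (1-c)\,e^{-\gamma_2 d}}.
#' Because the mixture weights sum to one, the kernel keeps the
#' normalisation \eqn{K(0) = 1} and the (0, 1] range of a single RBF,
#' while a small \eqn{\gamma_2} yields a heavier tail.
#'
#' @param sqDist non-negative squared distance(s); vectorised.
#' @param params a [KernelParams-class].
#' @return kernel value(s) in (0, 1].
#' @examples
#' doubleRbfKernel(1, KernelParams(gamma1 = 1, gamma2 = 0.1, c = 0.5))
#' @export
doubleRbfKernel <- function(sqDist, params) {
    validObject(params)
    .checkSqDist(sqDist)
    params@c * exp(-params@gamma1 * sqDist) +
        (1 - params@c) * exp(-params@gamma2 * sqDist)
}

#' Kernel-induced squared distance between two per-gene values
#'
#' The feature-space squared distance obtained through the kernel trick,
#' \deqn{\|\Phi(a) - \Phi(b)\|^2 = K(a,a) - 2K(a,b) + K(b,b),}
#' which for any kernel with \eqn{K(x,x) = 1} (both RBF forms here)
#' simplifies to \eqn{2(1 - K(a, b))}. Symmetric, zero iff \eqn{a = b},
#' and strictly below 2 for finite inputs; it saturates at 2 as
#' \eqn{|a - b| \to \infty} (exponent underflow is harmless: the distance
#' simply reaches 2 exactly).
#'
#' @param a,b scalar per-gene values; vectorised elementwise.
#' @param params a [KernelParams-class].
#' @return squared feature-space distance(s) in [0, 2).
#' @examples
#' kernelSqDistance(0, 1, KernelParams())
#' @export
kernelSqDistance <- function(a, b, params) {
    2 * (1 - doubleRbfKernel((a - b)^2, params))
}
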