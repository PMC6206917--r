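# Small in-code fixtures shared across the suite.

# 4 samples x 3 genes, two classes, hand-checkable values.
tinySet <- function() {
    m <- matrix(c(0, 2, 4, 6,
                  1, 1, 3, 3,
                  5, 5, 5, 5),
                nrow = 4, dimnames = list(paste0("s", 1:4),
                                          paste0("g", 1:3)))
    GeneExpressionSet(m, labels = c("A", "A", "B", "B"))
}

# A well-separated two-class set for classifier sanity checks.
separableSet <- function(n = 30, l = 20, shift = 6, seed = 42) {
    set.seed(seed)
    m <- matrix(rnorm(n * l), n, l)
    half <- seq_len(n / 2)
    m[half, 1:5] <- m[half, 1:5] + shift
    GeneExpressionSet(m, labels = rep(c("pos", "neg"), each = n / 2))
}

randomKernelParams <- function() {
    KernelParams(gamma1 = runif(1, 0.05, 4), gamma2 = runif(1, 0.05, 4),
                 c = runif(1))
}

# Dense simplex grid with the given step, as an m x l matrix (l <= 3).
simplexGrid <- function(l, step = 1e-3) {
    s <- seq(0, 1, by = step)
    if (l == 2L) {
        cbind(s, 1 - s)
    } else if (l == 3L) {
        g <- expand.grid(w1 = s, w2 = s)
        g <- g[g$w1 + g$w2 <= 1 + 1e-12, ]
        cbind(g$w1, g$w2, pmax(0, 1 - g$w1 - g$w2))
    } else stop("grid oracle only for l <= 3")
}

# Brute-force minimum of J(w) = w.D + delta * ||w||^2 over the grid.
gridMinObjective <- function(D, delta, step = 1e-3) {
    G <- simplexGrid(length(D), step)
    min(as.numeric(G %*% D) + delta * rowSums(G^2))
}
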