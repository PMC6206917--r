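test_that("class centroids are gene-wise class means in appearance order", {
    ds <- tinySet()
    ctr <- computeCenters(zscoreNormalize(ds)$data)
    expect_identical(ctr@classOrder, c("A", "B"))
    expect_identical(ctr@classSizes, c(2L, 2L))

    # hand-computed on the raw fixture
    raw <- computeCenters(exprMatrix(ds), classLabels(ds))
    expect_equal(unname(raw@centers),
                 rbind(c(1, 1, 5), c(5, 3, 5)))

    # singleton class: centre equals the sample itself
    m <- matrix(rnorm(6), 3, 2)
    one <- computeCenters(m, c("A", "A", "B"))
    expect_equal(unname(one@centers["B", ]), unname(m[3, ]))
    expect_error(computeCenters(m, c("A", "A", "A")), "2 classes")
})

test_that("per-gene dissimilarity matches a brute-force double loop", {
    set.seed(21)
    m <- matrix(rnorm(8), 4, 2)
    lab <- c("A", "A", "B", "B")
    p <- KernelParams(gamma1 = 1, gamma2 = 1, c = 1)  # single RBF
    ctr <- computeCenters(m, lab)
    D <- perGeneDissimilarity(m, ctr, p, lab)
    brute <- numeric(2)
    for (k in 1:2)
        for (j in 1:4) {
            v <- ctr@centers[ifelse(j <= 2, "A", "B"), k]
            brute[k] <- brute[k] + 2 * (1 - exp(-(m[j, k] - v)^2))
        }
    expect_equal(unname(D), brute, tolerance = 1e-12)

    # samples identical to their centres: D = 0; always D_k < 2n
    same <- matrix(rep(c(1, 4), each = 2), 4, 2)
    ctr2 <- computeCenters(same, lab)
    expect_equal(unname(perGeneDissimilarity(same, ctr2, p, lab)),
                 c(0, 0))
    big <- matrix(rnorm(200, sd = 50), 10, 20)
    labs <- rep(c("A", "B"), 5)
    Dbig <- perGeneDissimilarity(big, labels = labs,
                                 params = KernelParams())
    expect_true(all(Dbig >= 0 & Dbig < 2 * 10))
})

test_that("the closed-form weight update solves the simplex problem", {
    # hand example: raw update already feasible
    w <- updateWeights(c(0, 2), delta = 1)
    expect_equal(unname(weightValues(w)), c(1, 0))
    # equal dissimilarities give uniform weights
    expect_equal(unname(weightValues(updateWeights(rep(3.3, 5), 0.7))),
                 rep(0.2, 5))
    # weight is non-increasing in D and ranking follows ascending D
    set.seed(22)
    D <- runif(30, 0, 8)
    w <- weightValues(updateWeights(D, delta = 2))
    expect_true(all(diff(w[order(D)]) <= 1e-12))
    expect_error(updateWeights(D, delta = 0), "positive")
    expect_error(updateWeights(c(-1, 1), delta = 1), "non-negative")
})

test_that("the update attains the grid minimum of the objective (l = 2, 3)", {
    set.seed(23)
    for (i in 1:40) {
        l <- sample(2:3, 1)
        D <- runif(l, 0, 10)
        delta <- runif(1, 0.02, 1.5) * sum(D)
        w <- weightValues(updateWeights(D, delta))
        expect_lt(abs(sum(w) - 1), 1e-10)
        expect_true(all(w >= 0))
        ours <- objectiveValue(D, w, delta)
        gmin <- gridMinObjective(D, delta, step = 2e-3)
        # exact minimiser can only improve on the grid minimum
        expect_lte(ours, gmin + 1e-12)
        expect_lt(gmin - ours, (max(D) + 2 * delta) * 2e-3 * l)
    }
})

test_that("delta schedules obey their algebraic identities", {
    set.seed(24)
    D <- runif(10, 0, 5)
    uni <- rep(0.1, 10)
    expect_equal(updateDelta(D, uni), sum(D), tolerance = 1e-12)
    expect_equal(updateDelta(D, uni, variant = "kbcgs", alpha = 0.05),
                 0.05 * sum(D), tolerance = 1e-12)
    expect_equal(updateDelta(c(1, 3), c(0.5, 0.5)), 4)
    expect_equal(updateDelta(c(1, 3), c(0.5, 0.5), "kbcgs", 0.05), 0.2)
    expect_equal(updateDelta(c(7, 2), c(1, 0)), 7)  # one-hot
    # alpha linearity
    expect_equal(updateDelta(D, uni, "kbcgs", 0.2),
                 2 * updateDelta(D, uni, "kbcgs", 0.1))
    expect_equal(updateDelta(D, uni, "kbcgs", 1), updateDelta(D, uni))
    expect_error(updateDelta(c(0, 0), c(0.5, 0.5)), "vanish")
})

test_that("the objective follows its closed forms", {
    set.seed(25)
    D <- runif(6, 0, 4)
    l <- length(D)
    uni <- rep(1 / l, l)
    expect_equal(objectiveValue(D, uni, sum(D)), 2 * sum(D) / l,
                 tolerance = 1e-12)
    onehot <- as.numeric(seq_len(l) == which.min(D))
    expect_equal(objectiveValue(D, onehot, 0.9), min(D) + 0.9)
    expect_equal(objectiveValue(rep(0, l), uni, 2), 2 / l)
    # J >= delta / l on the simplex
    for (i in 1:20) {
        w <- runif(l); w <- w / sum(w)
        expect_gte(objectiveValue(D, w, 1.3), 1.3 / l - 1e-12)
    }
})

test_that("the optimiser keeps its loop contract on synthetic data", {
    sim <- simulateExpression(SyntheticSpec(30, 80, 2, nInformative = 5,
                                            seed = 5))
    sel <- selectGenes(sim$dataset)
    st <- sel@state
    expect_true(st@converged)
    expect_lte(st@t, 100L)
    expect_lt(abs(st@objectiveTrace[st@t] - st@objectiveTrace[st@t - 1]),
              1e-6)
    w <- weightValues(sel)
    expect_lt(abs(sum(w) - 1), 1e-10)
    expect_true(all(w >= 0))
    # ranking by weight equals ranking by ascending dissimilarity
    expect_identical(geneRanking(sel),
                     order(sel@dissimilarity,
                           seq_along(sel@dissimilarity)))
})

test_that("selection is equivariant to gene permutation and invariant to sample order", {
    sim <- simulateExpression(SyntheticSpec(24, 40, 2, nInformative = 4,
                                            seed = 8))
    m <- exprMatrix(sim$dataset)
    lab <- as.character(classLabels(sim$dataset))
    base <- weightValues(selectGenes(m, lab))
    set.seed(9)
    pg <- sample(ncol(m))
    perm <- weightValues(selectGenes(m[, pg], lab))
    expect_equal(unname(perm), unname(base[pg]), tolerance = 1e-12)
    ps <- sample(nrow(m))
    shuf <- weightValues(selectGenes(m[ps, ], lab[ps]))
    expect_equal(unname(shuf), unname(base), tolerance = 1e-12)
})

test_that("degenerate shapes and variants behave as specified", {
    # single gene: trivial simplex
    m1 <- matrix(c(1, 2, 3, 4), 4, 1)
    sel1 <- selectGenes(m1, c("A", "A", "B", "B"))
    expect_equal(unname(weightValues(sel1)), 1)
    expect_true(sel1@state@converged)
    expect_identical(sel1@state@t, 0L)

    # duplicated gene columns get equal weights
    set.seed(10)
    m <- matrix(rnorm(40), 10, 4)
    m <- cbind(m, m[, 2])
    sel <- selectGenes(m, rep(c("A", "B"), 5))
    w <- unname(weightValues(sel))
    expect_lt(abs(w[2] - w[5]), 1e-10)

    # kbcgs with alpha = 1 traces dkbcgs exactly
    a <- selectGenes(m, rep(c("A", "B"), 5), variant = "kbcgs", alpha = 1)
    b <- selectGenes(m, rep(c("A", "B"), 5), variant = "dkbcgs")
    expect_equal(a@state@objectiveTrace, b@state@objectiveTrace,
                 tolerance = 1e-12)
    expect_equal(weightValues(a), weightValues(b), tolerance = 1e-12)

    # perfectly class-separated-per-gene data degenerates with a warning
    sep <- matrix(rep(c(0, 0, 1, 1), 2), 4, 2)
    expect_warning(s <- selectGenes(sep, c("A", "A", "B", "B")),
                   "vanish")
    expect_false(s@state@converged)
    expect_equal(unname(weightValues(s)), c(0.5, 0.5))
})
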