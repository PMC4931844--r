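test_that("Miller-Madow entropy matches the two-term formula", {
    expect_equal(millerMadowEntropy(4), 0)
    expect_equal(millerMadowEntropy(c(2, 2)), log(2) + 1 / 8,
        tolerance = 1e-12)
    expect_equal(millerMadowEntropy(c(1, 1)), log(2) + 1 / 4,
        tolerance = 1e-12)
    expect_error(millerMadowEntropy(c(0, 0)), "empty distribution")
    expect_error(millerMadowEntropy(c(-1, 2)), "non-negative")
})

test_that("MI combines three Miller-Madow entropies with clamping", {
    expect_equal(miMillerMadow(c(0, 0, 1, 1), c(0, 0, 1, 1)),
        log(2) + 1 / 8, tolerance = 1e-12)
    # independent-looking pattern: raw value negative, clamped to zero
    expect_identical(miMillerMadow(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
    expect_equal(miMillerMadow(c(0, 0, 1, 1), c(0, 1, 0, 1), clamp = FALSE),
        2 * (log(2) + 1 / 8) - (log(4) + 3 / 8), tolerance = 1e-12)
    # a constant variable carries no information
    expect_identical(miMillerMadow(c(0, 0, 0, 0), c(0, 1, 2, 1)), 0)
    expect_error(miMillerMadow(c(0, 1), c(0, 1, 0)), "same length")
})

test_that("entropy and MI equal brute-force contingency computation", {
    # every count vector over up to 4 cells summing to <= 8
    for (m in 1:4) {
        grid <- expand.grid(rep(list(0:8), m))
        grid <- grid[rowSums(grid) >= 1 & rowSums(grid) <= 8, , drop = FALSE]
        for (r in seq_len(nrow(grid))) {
            cts <- as.numeric(grid[r, ])
            expect_equal(millerMadowEntropy(cts), oracleEntropy(cts),
                tolerance = 1e-12)
        }
    }
    # all pairs of length-4 bin vectors over {0,1,2}
    vecs <- as.matrix(expand.grid(0:2, 0:2, 0:2, 0:2))
    for (i in seq_len(nrow(vecs))) {
        xb <- vecs[i, ]
        for (j in seq_len(nrow(vecs))) {
            yb <- vecs[j, ]
            expect_equal(miMillerMadow(xb, yb), oracleMI(xb, yb),
                tolerance = 1e-12)
        }
    }
    # seeded random pairs of length 5..8 over larger alphabets
    set.seed(42)
    for (r in 1:500) {
        n <- sample(5:8, 1)
        xb <- sample(0:3, n, replace = TRUE)
        yb <- sample(0:3, n, replace = TRUE)
        expect_equal(miMillerMadow(xb, yb, clamp = FALSE),
            oracleMI(xb, yb, clamp = FALSE), tolerance = 1e-12)
    }
})

test_that("MI estimates are consistent at cube-root binning", {
    # bivariate Gaussian rho = 0.8: analytic MI = 0.5108 nats; joint
    # tables need n >> B^2, hence cube-root bins for this check
    est <- vapply(1:20, function(s) {
        set.seed(s)
        x <- stats::rnorm(2000)
        y <- 0.8 * x + 0.6 * stats::rnorm(2000)
        B <- max(2L, floor(2000^(1 / 3)))
        miMillerMadow(discretize(x, B), discretize(y, B))
    }, numeric(1))
    expect_lt(abs(stats::median(est) - 0.5108), 0.2 * 0.5108)
})

test_that("adding independent noise never raises median estimated MI", {
    med <- vapply(c(0, 0.5, 1, 2), function(ns) {
        stats::median(vapply(1:50, function(s) {
            set.seed(s)
            x <- stats::rnorm(200)
            y <- x + ns * stats::rnorm(200)
            miMillerMadow(discretize(x, 14), discretize(y, 14))
        }, numeric(1)))
    }, numeric(1))
    expect_true(all(diff(med) <= 1e-9))
})
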