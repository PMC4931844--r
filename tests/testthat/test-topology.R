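test_that("node strength sums incident weights", {
    tri <- geneNetwork(symMat(3, c(1, 1, 1)))
    expect_equal(unname(nodeStrength(tri)), c(2, 2, 2))
    a <- symMat(3, c(0.5, 0.3, 0))     # g1-g2 .5, g1-g3 .3
    expect_equal(unname(nodeStrength(geneNetwork(a))["g1"]), 0.8)
    iso <- geneNetwork(matrix(0, 3, 3))
    expect_equal(unname(nodeStrength(iso)), c(0, 0, 0))
})

test_that("Barrat clustering matches brute-force triple loops", {
    # closed unit triangle: coefficient 1 at every node
    expect_equal(unname(weightedClustering(geneNetwork(symMat(3, c(1, 1, 1))))),
        c(1, 1, 1))
    # star center has no closed triangles
    star <- matrix(0, 5, 5)
    star[1, 2:5] <- star[2:5, 1] <- 1
    expect_equal(unname(weightedClustering(geneNetwork(star))[1]), 0)
    # random weighted graphs vs oracle
    for (s in 1:15) {
        set.seed(s)
        p <- sample(5:20, 1)
        A <- matrix(0, p, p)
        up <- upper.tri(A)
        w <- stats::runif(sum(up)) * (stats::runif(sum(up)) < 0.4)
        A[up] <- w
        A <- A + t(A)
        rownames(A) <- colnames(A) <- sprintf("g%d", 1:p)
        net <- geneNetwork(A)
        expect_equal(unname(weightedClustering(net)), oracleBarrat(A),
            tolerance = 1e-12)
        expect_equal(unname(nodeStrength(net)), unname(rowSums(A)),
            tolerance = 1e-12)
        ci <- weightedClustering(net)
        expect_true(all(ci >= 0 & ci <= 1 + 1e-12))
    }
})

test_that("hierarchy verdicts separate nested cliques from random graphs", {
    nc <- generateReferenceNetwork("nested_cliques", 125, param = 3)
    hn <- hierarchyDiagnostic(nc)
    expect_identical(hn$verdict, "yes")
    expect_lt(hn$rho, 0)
    er <- generateReferenceNetwork("random", 400, param = 10 / 399, seed = 1)
    expect_identical(hierarchyDiagnostic(er)$verdict, "no")
    # degenerate: all coefficients equal -> inconclusive, not an error
    expect_warning(
        h0 <- hierarchyDiagnostic(strength = stats::runif(20),
            clustering = rep(0.5, 20)),
        "inconclusive")
    expect_identical(h0$verdict, "inconclusive")
    expect_warning(
        hs <- hierarchyDiagnostic(generateReferenceNetwork("two_cliques", 6)),
        "only")
    expect_identical(hs$verdict, "inconclusive")
})

test_that("power-law fitting recovers a Pareto exponent", {
    set.seed(1)
    x <- (1 - stats::runif(1000))^(-1 / (2.5 - 1))
    f <- fitPowerLaw(x)
    expect_gt(f$alpha, 2.3)
    expect_lt(f$alpha, 2.7)
})

test_that("scale-free verdicts separate uniform strengths from power laws", {
    set.seed(2)
    sf <- scaleFreeDiagnostic(stats::runif(400, 1, 2), nBoot = 100, seed = 1)
    expect_identical(sf$verdict, "no")
    set.seed(3)
    pareto <- (1 - stats::runif(400))^(-1 / 1.5)
    sfp <- scaleFreeDiagnostic(pareto, nBoot = 100, seed = 1)
    expect_identical(sfp$verdict, "yes")
    expect_error(scaleFreeDiagnostic(stats::runif(10)), "at least 20")
    expect_message(
        scaleFreeDiagnostic(c(rep(0, 5), pareto), nBoot = 10, seed = 1),
        "excluded 5")
})

test_that("eigenvector centrality matches the dominant eigenpair", {
    a <- symMat(3, c(1, 0, 1))  # path g1-g2-g3
    prof <- eigenvectorCentrality(geneNetwork(a))
    expect_equal(unname(centralities(prof)),
        c(sqrt(0.5), 1, sqrt(0.5)), tolerance = 1e-9)
    full <- matrix(0.7, 4, 4)
    diag(full) <- 0
    expect_equal(unname(centralities(eigenvectorCentrality(geneNetwork(full)))),
        rep(1, 4), tolerance = 1e-9)
    expect_error(eigenvectorCentrality(geneNetwork(matrix(0, 3, 3))),
        "centrality undefined")
})

test_that("centrality agrees with a power-iteration oracle", {
    for (s in 1:10) {
        set.seed(s)
        p <- sample(6:15, 1)
        A <- matrix(0, p, p)
        up <- upper.tri(A)
        A[up] <- stats::runif(sum(up))
        A <- A + t(A)          # dense: connected
        diag(A) <- 0
        rownames(A) <- colnames(A) <- sprintf("g%d", 1:p)
        prof <- eigenvectorCentrality(geneNetwork(A))
        pi <- oraclePowerIteration(A)
        expect_equal(unname(centralities(prof)),
            pi$vector / max(pi$vector), tolerance = 1e-8)
        expect_equal(dominantEigenvalue(prof), pi$lambda,
            tolerance = 1e-8)
        # invariance to uniform weight rescaling
        prof2 <- eigenvectorCentrality(geneNetwork(A * 7.3))
        expect_equal(centralities(prof2), centralities(prof),
            tolerance = 1e-9)
    }
})

test_that("disconnected graphs use the dominant component with a warning", {
    A <- matrix(0, 5, 5)
    A[1, 2] <- A[2, 1] <- 3      # strong pair
    A[3, 4] <- A[4, 3] <- 1
    rownames(A) <- colnames(A) <- sprintf("g%d", 1:5)
    expect_warning(prof <- eigenvectorCentrality(geneNetwork(A)),
        "disconnected")
    v <- centralities(prof)
    expect_equal(unname(v[1:2]), c(1, 1))
    expect_equal(unname(v[3:5]), c(0, 0, 0))
})

test_that("central genes are thresholded on the max-1 scale", {
    prof <- new("CentralityProfile",
        centrality = c(a = 1, b = 0.95, c = 0.3),
        eigenvalue = 2, component = 1:3)
    expect_identical(identifyCentralGenes(prof, 0.9), c("a", "b"))
    expect_identical(identifyCentralGenes(prof, 1), "a")
    expect_error(identifyCentralGenes(prof, 0), "tau")
})

test_that("a planted hub is identified as a central gene", {
    se <- smallStudy(5)
    net <- aracne(buildMIM(se))
    prof <- suppressWarnings(eigenvectorCentrality(net))
    hubs <- S4Vectors::metadata(se)$truth$hubs
    expect_true(any(hubs %in% identifyCentralGenes(prof, 0.9)))
    expect_true(names(which.max(centralities(prof))) %in% hubs)
})
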