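test_that("spec validation names the offending field", {
    expect_error(syntheticSpec(nGenes = 10, clusterSizes = c(4, 4)),
        "clusterSizes")
    expect_error(syntheticSpec(nGenes = 10, nClusters = 2,
        treatmentLevels = c("a", "b"), samplesPerLevel = c(5, 5, 5),
        rewireFraction = c(0, 0)), "samplesPerLevel")
    expect_error(syntheticSpec(nGenes = 10, nClusters = 2,
        treatmentLevels = "a", samplesPerLevel = 5,
        rewireFraction = 1.4), "fractions")
    expect_error(syntheticSpec(noiseSd = 0), "noiseSd")
    expect_error(syntheticSpec(nGenes = 10, nClusters = 2,
        treatmentLevels = "a", samplesPerLevel = 5, rewireFraction = 0,
        hubGenes = 11L), "hubGenes")
})

test_that("generation is byte-identical for identical spec and seed", {
    sp <- syntheticSpec(nGenes = 30, nClusters = 3,
        samplesPerLevel = c(6, 6, 7, 5, 5, 8), seed = 9)
    se1 <- generateExpression(sp)
    se2 <- generateExpression(sp)
    expect_identical(SummarizedExperiment::assay(se1),
        SummarizedExperiment::assay(se2))
    expect_identical(S4Vectors::metadata(se1)$truth,
        S4Vectors::metadata(se2)$truth)
    expect_true(all(SummarizedExperiment::assay(se1) > 0))
})

test_that("zero rewiring keeps assignments identical at every level", {
    sp <- syntheticSpec(nGenes = 40, nClusters = 2,
        treatmentLevels = c("a", "b", "c"),
        samplesPerLevel = c(5, 5, 5), rewireFraction = c(0, 0, 0),
        seed = 1)
    tr <- S4Vectors::metadata(generateExpression(sp))$truth
    expect_identical(tr$assignments[, 1], tr$assignments[, 2])
    expect_identical(tr$assignments[, 1], tr$assignments[, 3])
    expect_identical(unname(tr$assignments[, 1]), unname(tr$base))
})

test_that("the rewired fraction matches the spec within one gene", {
    sp <- syntheticSpec(nGenes = 100, nClusters = 4,
        treatmentLevels = c("a", "b", "c"),
        samplesPerLevel = c(5, 5, 5),
        rewireFraction = c(0, 0.1, 0.3), seed = 2)
    tr <- S4Vectors::metadata(generateExpression(sp))$truth
    for (l in 1:3) {
        moved <- sum(tr$assignments[, l] != tr$base)
        expect_lte(abs(moved - round(sp@rewireFraction[l] * 100)), 1)
    }
})

test_that("the noise-free single-cluster limit is perfectly rank-correlated", {
    sp <- syntheticSpec(nGenes = 10, nClusters = 1,
        treatmentLevels = "A", samplesPerLevel = 50L,
        rewireFraction = 0, hubGenes = integer(0),
        nonmonotoneFraction = 0, noiseSd = 1e-6, seed = 2)
    r <- stats::cor(t(SummarizedExperiment::assay(generateExpression(sp))),
        method = "spearman")
    expect_true(all(abs(r) >= 0.99))
})

test_that("within-cluster dependence exceeds between-cluster dependence", {
    sp <- syntheticSpec(nGenes = 60, nClusters = 3,
        treatmentLevels = "A", samplesPerLevel = 100L,
        rewireFraction = 0, hubGenes = integer(0),
        nonmonotoneFraction = 0, noiseSd = 0.3, seed = 7)
    se <- generateExpression(sp)
    r <- abs(stats::cor(t(SummarizedExperiment::assay(se)),
        method = "spearman"))
    diag(r) <- NA
    base <- S4Vectors::metadata(se)$truth$base
    same <- outer(base, base, "==")
    expect_gt(mean(r[same], na.rm = TRUE), mean(r[!same], na.rm = TRUE))
})

test_that("planted non-monotone pairs are Spearman-null but MI-positive", {
    sp <- syntheticSpec(nGenes = 30, nClusters = 3,
        treatmentLevels = "A", samplesPerLevel = 200L,
        rewireFraction = 0, nonmonotoneFraction = 0.25, noiseSd = 0.25,
        seed = 6)
    se <- generateExpression(sp)
    pr <- S4Vectors::metadata(se)$truth$nonmonotonePairs
    expect_gt(nrow(pr), 0)
    X <- SummarizedExperiment::assay(se)
    rho <- abs(stats::cor(t(X), method = "spearman"))
    expect_lt(mean(rho[cbind(pr$gene1, pr$gene2)]), 0.15)
    # binned MI of a planted pair beats a permutation null
    x <- X[pr$gene1[1], ]
    y <- X[pr$gene2[1], ]
    B <- defaultBins(length(x))
    obs <- miMillerMadow(discretize(x, B), discretize(y, B))
    null <- vapply(1:200, function(b) {
        set.seed(b)
        miMillerMadow(discretize(x, B), discretize(sample(y), B))
    }, numeric(1))
    expect_gt(obs, stats::quantile(null, 0.95))
})

test_that("differentially expressed genes shift gradually with level", {
    sp <- syntheticSpec(nGenes = 100, nClusters = 4,
        treatmentLevels = c("a", "b", "c"),
        samplesPerLevel = c(40, 40, 40), rewireFraction = c(0, 0, 0),
        factorTrend = 0, deFraction = 0.2, deMagnitude = 1.5,
        noiseSd = 0.3, seed = 4)
    se <- generateExpression(sp)
    tr <- S4Vectors::metadata(se)$truth
    expect_length(tr$deGenes, 20)
    X <- log(SummarizedExperiment::assay(se))
    trt <- SummarizedExperiment::colData(se)$treatment
    for (g in tr$deGenes[1:5]) {
        mLev <- tapply(X[g, ], trt, mean)
        drift <- mLev[3] - mLev[1]
        expect_equal(unname(sign(drift)), unname(sign(tr$deShift[g])))
        expect_gt(abs(drift), 0.2)
    }
    # non-DE genes do not drift systematically
    other <- setdiff(rownames(X), tr$deGenes)
    drifts <- vapply(other, function(g) {
        mLev <- tapply(X[g, ], trt, mean)
        mLev[3] - mLev[1]
    }, numeric(1))
    expect_lt(stats::median(abs(drifts)), 0.35)
})

test_that("reference network kinds honour their constructions", {
    tc <- generateReferenceNetwork("two_cliques", 6)
    s <- networkSummary(tc)
    expect_identical(s$edges, 6L)
    expect_identical(s$components, 2)
    pa <- generateReferenceNetwork("scale_free", 1000, param = 2, seed = 1)
    deg <- rowSums(adjacency(pa) > 0)
    expect_gte(max(deg), 10 * stats::median(deg))
    # determinism under seed
    pa2 <- generateReferenceNetwork("scale_free", 1000, param = 2, seed = 1)
    expect_identical(adjacency(pa), adjacency(pa2))
    expect_error(generateReferenceNetwork("random", 0), "nNodes")
    expect_error(generateReferenceNetwork("smallworld", 10),
        "scale_free.*random.*two_cliques.*nested_cliques")
})
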