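twoTriangles <- function() {
    A <- matrix(0, 6, 6, dimnames = list(sprintf("g%d", 1:6),
        sprintf("g%d", 1:6)))
    for (o in c(0, 3)) {
        ix <- o + 1:3
        A[ix, ix] <- 1
    }
    diag(A) <- 0
    geneNetwork(A)
}

test_that("modularity of two disjoint triangles under the natural split is 1/2", {
    net <- twoTriangles()
    expect_equal(modularityCoefficient(net, rep(1:2, each = 3)), 0.5,
        tolerance = 1e-12)
    # one big cluster: within-sum equals its random expectation
    expect_equal(modularityCoefficient(net, rep(1L, 6)), 0,
        tolerance = 1e-12)
    expect_error(modularityCoefficient(geneNetwork(matrix(0, 3, 3)),
        rep(1L, 3)), "empty network")
})

test_that("modularity equals brute-force double-loop evaluation", {
    for (s in 1:20) {
        set.seed(s)
        p <- sample(4:12, 1)
        A <- matrix(0, p, p)
        up <- upper.tri(A)
        A[up] <- stats::runif(sum(up)) * (stats::runif(sum(up)) < 0.6)
        A <- A + t(A)
        rownames(A) <- colnames(A) <- sprintf("g%d", 1:p)
        if (sum(A) == 0) next
        memb <- sample(1:3, p, replace = TRUE)
        net <- geneNetwork(A)
        q <- modularityCoefficient(net, memb)
        expect_equal(q, oracleModularity(A, memb), tolerance = 1e-12)
        # igraph as an independent implementation
        expect_equal(q, igraph::modularity(crnet:::.asIgraph(net), memb,
            weights = igraph::E(crnet:::.asIgraph(net))$weight),
            tolerance = 1e-10)
        # invariance to relabeling and uniform rescaling
        relab <- c(7, 2, 9)[memb]
        expect_equal(modularityCoefficient(net, relab), q,
            tolerance = 1e-12)
        expect_equal(modularityCoefficient(geneNetwork(A * 3.7), memb), q,
            tolerance = 1e-12)
    }
})

test_that("community detection finds the natural split of disjoint triangles", {
    pt <- detectCommunities(twoTriangles(), seed = 4)
    expect_identical(nClusters(pt), 2L)
    expect_equal(modularityQ(pt), 0.5, tolerance = 1e-12)
    full <- matrix(0.4, 5, 5)
    diag(full) <- 0
    ptf <- detectCommunities(geneNetwork(full), seed = 1)
    expect_identical(nClusters(ptf), 1L)
    expect_error(detectCommunities(geneNetwork(matrix(0, 4, 4))),
        "empty network")
})

test_that("detected partitions never score below trivial baselines", {
    for (s in 1:15) {
        set.seed(s)
        p <- 12
        A <- matrix(0, p, p)
        up <- upper.tri(A)
        A[up] <- stats::runif(sum(up)) * (stats::runif(sum(up)) < 0.3)
        A <- A + t(A)
        rownames(A) <- colnames(A) <- sprintf("g%d", 1:p)
        if (sum(A) == 0) next
        net <- geneNetwork(A)
        pt <- detectCommunities(net, seed = s)
        single <- stats::setNames(seq_len(p), rownames(A))
        expect_gte(modularityQ(pt), 0)
        expect_gte(modularityQ(pt), modularityCoefficient(net, single))
        expect_equal(modularityQ(pt),
            modularityCoefficient(net, clusterAssignments(pt)),
            tolerance = 1e-12)
    }
})

test_that("planted clusters are recovered from synthetic expression", {
    se <- smallStudy(11, noise = 0.2)
    net <- aracne(buildMIM(se), epsilon = 0.2)
    pt <- detectCommunities(net, seed = 11)
    ari <- adjustedRand(clusterAssignments(pt),
        S4Vectors::metadata(se)$truth$base)
    expect_gte(ari, 0.9)
})

test_that("adjusted Rand agrees with pair counting and handles relabeling", {
    expect_equal(adjustedRand(rep(1:2, 5), rep(1:2, 5)), 1)
    expect_equal(adjustedRand(rep(1:2, 5), rep(c(9, 4), 5)), 1)
    set.seed(2)
    a <- sample(1:4, 100, replace = TRUE)
    b <- a
    flip <- sample(100, 10)
    b[flip] <- sample(1:4, 10, replace = TRUE)
    expect_equal(adjustedRand(a, b), oracleARI(a, b), tolerance = 1e-12)
})

test_that("cluster crosstabs report flows and catch gene mismatches", {
    p1 <- stats::setNames(rep(1:2, each = 5), sprintf("g%d", 1:10))
    p2 <- stats::setNames(c(rep(1, 4), 2, rep(2, 5)), sprintf("g%d", 1:10))
    fl <- clusterCrosstab(list(a = p1, b = p2, c = p2))
    expect_length(fl, 2)
    expect_equal(fl[[2]]$ari, 1)
    expect_equal(fl[[1]]$ari, oracleARI(p1, p2), tolerance = 1e-12)
    expect_identical(sum(fl[[1]]$table), 10L)
    bad <- stats::setNames(rep(1, 10), sprintf("x%d", 1:10))
    expect_error(clusterCrosstab(list(p1, bad)), "different genes")
})
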