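# Independent brute-force oracles, deliberately written as plain loops
# over explicitly materialized tables so they share no code path with
# the package implementations.

# entropy from an explicitly materialized contingency table
oracleEntropy <- function(counts) {
    n <- sum(counts)
    h <- 0
    for (cc in counts) {
        if (cc > 0)
            h <- h - (cc / n) * log(cc / n)
    }
    m <- sum(counts > 0)
    h + (m - 1) / (2 * n)
}

# MI by triple-entropy over materialized 1-D and 2-D tables
oracleMI <- function(xb, yb, clamp = TRUE) {
    ux <- sort(unique(xb))
    uy <- sort(unique(yb))
    tx <- vapply(ux, function(a) sum(xb == a), numeric(1))
    ty <- vapply(uy, function(b) sum(yb == b), numeric(1))
    txy <- matrix(0, length(ux), length(uy))
    for (i in seq_along(ux))
        for (j in seq_along(uy))
            txy[i, j] <- sum(xb == ux[i] & yb == uy[j])
    i <- oracleEntropy(tx) + oracleEntropy(ty) - oracleEntropy(as.vector(txy))
    if (clamp) max(i, 0) else i
}

# exhaustive-triplet ARACNE: marks against the original matrix, then
# simultaneous removal
oracleAracne <- function(M, epsilon = 0) {
    p <- nrow(M)
    keep <- M > 0
    for (i in seq_len(p)) for (j in seq_len(p)) for (k in seq_len(p)) {
        if (i == j || j == k || i == k) next
        if (M[i, j] > 0 && M[i, k] > 0 && M[j, k] > 0 &&
            M[i, j] < min(M[i, k], M[j, k]) - epsilon)
            keep[i, j] <- FALSE
    }
    out <- M
    out[!keep] <- 0
    out
}

# modularity by explicit double loop over ordered node pairs (i = j
# included, as in the null model)
oracleModularity <- function(A, memb) {
    W2 <- sum(A)
    s <- unname(rowSums(A))
    q <- 0
    p <- nrow(A)
    for (i in seq_len(p)) for (j in seq_len(p)) {
        if (memb[i] == memb[j])
            q <- q + A[i, j] / W2 - s[i] * s[j] / W2^2
    }
    q
}

# adjusted Rand index by pair counting
oracleARI <- function(a, b) {
    n <- length(a)
    n11 <- n00 <- n10 <- n01 <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        sa <- a[i] == a[j]
        sb <- b[i] == b[j]
        if (sa && sb) n11 <- n11 + 1
        else if (!sa && !sb) n00 <- n00 + 1
        else if (sa) n10 <- n10 + 1
        else n01 <- n01 + 1
    }
    np <- n11 + n00 + n10 + n01
    expected <- (n11 + n10) * (n11 + n01) / np
    maxidx <- ((n11 + n10) + (n11 + n01)) / 2
    if (maxidx == expected) return(1)
    (n11 - expected) / (maxidx - expected)
}

# dominant eigenvector by power iteration on a connected component
oraclePowerIteration <- function(A, iter = 100000, tol = 1e-26) {
    v <- rep(1, nrow(A))
    for (i in seq_len(iter)) {
        v2 <- A %*% v
        v2 <- v2 / sqrt(sum(v2^2))
        if (sum((v2 - v)^2) < tol) break
        v <- v2
    }
    lambda <- as.numeric(t(v2) %*% A %*% v2)
    list(vector = abs(as.vector(v2)), lambda = lambda)
}

# Barrat clustering by explicit triple loop
oracleBarrat <- function(W) {
    p <- nrow(W)
    B <- W > 0
    ci <- numeric(p)
    for (i in seq_len(p)) {
        nb <- which(B[i, ])
        k <- length(nb)
        if (k < 2) next
        s <- sum(W[i, ])
        acc <- 0
        for (j in nb) for (h in nb) {
            if (j != h && B[j, h])
                acc <- acc + (W[i, j] + W[i, h]) / 2
        }
        ci[i] <- acc / (s * (k - 1))
    }
    ci
}

# named symmetric matrix from a vector of upper-triangle weights
symMat <- function(p, w) {
    M <- matrix(0, p, p, dimnames = list(sprintf("g%d", 1:p),
        sprintf("g%d", 1:p)))
    M[upper.tri(M)] <- w
    M + t(M)
}

# small synthetic study shortcut used across tests
smallStudy <- function(seed, nGenes = 60, nClusters = 3, n = 100,
    noise = 0.25, nonmono = 0, hubs = NULL, levels = "A",
    rewire = 0) {
    spec <- syntheticSpec(nGenes = nGenes, nClusters = nClusters,
        treatmentLevels = levels,
        samplesPerLevel = rep(n, length(levels)),
        rewireFraction = rep(rewire, length(levels)) *
            c(0, rep(1, length(levels) - 1)),
        hubGenes = hubs, nonmonotoneFraction = nonmono,
        noiseSd = noise, seed = seed)
    generateExpression(spec)
}
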