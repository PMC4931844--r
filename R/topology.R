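#' Node strength
#'
#' Row sums of the weighted adjacency: for a pruned network this is the
#' cumulative dependency each gene carries.
#'
#' @param net a \code{\linkS4class{GeneNetwork}}.
#' @return named numeric vector of strengths \eqn{s_i = \sum_j w_{ij}}.
#' @export
nodeStrength <- function(net) {
    stopifnot(is(net, "GeneNetwork"))
    rowSums(net@adjacency)
}

#' Barrat weighted clustering coefficient
#'
#' \deqn{c_i = \frac{1}{s_i (k_i - 1)} \sum_{j,h}
#'   \frac{w_{ij} + w_{ih}}{2} a_{ij} a_{ih} a_{jh}}
#' with the sum over ordered neighbour pairs, \eqn{s_i} the node
#' strength and \eqn{k_i} the (binary) degree; \eqn{c_i = 0} when
#' \eqn{k_i < 2}. Values lie in [0, 1] and reduce to the binary
#' clustering coefficient for unit weights.
#'
#' @param net a \code{\linkS4class{GeneNetwork}}.
#' @return named numeric vector of coefficients.
#' @export
weightedClustering <- function(net) {
    stopifnot(is(net, "GeneNetwork"))
    W <- net@adjacency
    B <- (W > 0) * 1
    k <- rowSums(B)
    s <- rowSums(W)
    # sum over ordered neighbour pairs (j,h): by j<->h symmetry this is
    # sum_j w_ij * (number of common neighbours of i and j)
    common <- B %*% B
    num <- rowSums(W * common)
    ci <- ifelse(k >= 2, num / (s * (k - 1)), 0)
    ci[!is.finite(ci)] <- 0
    names(ci) <- rownames(W)
    ci
}

#' Hierarchy diagnostic
#'
#' A hierarchical topology shows a negative relationship between the
#' clustering coefficient and node strength: tightly clustered genes
#' sit at the periphery while strong genes bridge clusters. The
#' diagnostic is the Spearman correlation of \eqn{c_i} against
#' \eqn{s_i} over nodes with degree >= 2; the verdict is "yes" when
#' \eqn{\rho < 0} with \eqn{p < 0.05}, "no" otherwise, and
#' "inconclusive" when fewer than \code{minNodes} nodes are eligible or
#' the correlation is undefined (e.g. all coefficients equal).
#'
#' @param net a \code{\linkS4class{GeneNetwork}}, or \code{NULL} if
#'   \code{strength} and \code{clustering} are given directly.
#' @param strength,clustering optional precomputed vectors.
#' @param minNodes minimum eligible nodes (default 10).
#' @return list with \code{rho}, \code{p}, \code{nEligible},
#'   \code{verdict}.
#' @export
hierarchyDiagnostic <- function(net = NULL, strength = NULL,
    clustering = NULL, minNodes = 10) {
    if (!is.null(net)) {
        strength <- nodeStrength(net)
        clustering <- weightedClustering(net)
        k <- rowSums(net@adjacency > 0)
        eligible <- k >= 2
    } else {
        eligible <- rep(TRUE, length(strength))
    }
    s <- strength[eligible]
    ci <- clustering[eligible]
    out <- list(rho = NA_real_, p = NA_real_, nEligible = length(s),
        verdict = "inconclusive")
    if (length(s) < minNodes) {
        warning(sprintf(
            "hierarchy diagnostic inconclusive: only %d nodes with degree >= 2",
            length(s)))
        return(out)
    }
    if (stats::sd(s) == 0 || stats::sd(ci) == 0) {
        warning("hierarchy diagnostic inconclusive: degenerate (constant) input")
        return(out)
    }
    ct <- suppressWarnings(
        stats::cor.test(ci, s, method = "spearman", exact = FALSE))
    out$rho <- unname(ct$estimate)
    out$p <- ct$p.value
    out$verdict <- if (out$rho < 0 && out$p < 0.05) "yes" else "no"
    out
}

#' Eigenvector centrality
#'
#' Eigen-decomposes the symmetric non-negative adjacency and takes the
#' eigenvector of the dominant eigenvalue, with the sign fixed so all
#' entries are non-negative (Perron-Frobenius) and rescaled to a
#' maximum of 1. On a disconnected graph the profile is computed on the
#' connected component whose dominant eigenvalue is largest; genes in
#' other components are set to 0 with a warning. Centrality is
#' invariant to uniform rescaling of the weights.
#'
#' @param net a \code{\linkS4class{GeneNetwork}} with at least one edge.
#' @return a \code{\linkS4class{CentralityProfile}}.
#' @examples
#' a <- matrix(0, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' a[1, 2] <- a[2, 1] <- a[2, 3] <- a[3, 2] <- 1
#' centralities(eigenvectorCentrality(geneNetwork(a)))  # 0.7071 1 0.7071
#' @export
eigenvectorCentrality <- function(net) {
    stopifnot(is(net, "GeneNetwork"))
    A <- net@adjacency
    if (all(A == 0))
        stop("centrality undefined: network has no edges")
    comp <- igraph::components(.asIgraph(net))
    best <- NULL
    bestLambda <- -Inf
    for (cid in seq_len(comp$no)) {
        idx <- which(comp$membership == cid)
        if (length(idx) < 2 || all(A[idx, idx] == 0))
            next
        ev <- eigen(A[idx, idx, drop = FALSE], symmetric = TRUE)
        if (ev$values[1] > bestLambda) {
            bestLambda <- ev$values[1]
            best <- list(idx = idx, vec = ev$vectors[, 1])
        }
    }
    v <- numeric(nrow(A))
    names(v) <- rownames(A)
    vec <- abs(best$vec)
    v[best$idx] <- vec / max(vec)
    if (length(best$idx) < nrow(A))
        warning(sprintf(
            "disconnected network: centrality computed on a %d-gene component, %d gene(s) set to 0",
            length(best$idx), nrow(A) - length(best$idx)))
    new("CentralityProfile", centrality = v, eigenvalue = bestLambda,
        component = as.integer(best$idx))
}

#' Identify central genes
#'
#' Genes whose eigenvector centrality (on the max-1 scale) reaches a
#' threshold \code{tau}, sorted by decreasing centrality. With
#' \code{tau = 1} only the argmax gene(s) are returned; the default
#' 0.9 returns the small group of genes with disproportionally large
#' centrality.
#'
#' @param profile a \code{\linkS4class{CentralityProfile}}.
#' @param tau threshold in (0, 1], default 0.9.
#' @return character vector of gene ids, decreasing centrality.
#' @export
identifyCentralGenes <- function(profile, tau = 0.9) {
    stopifnot(is(profile, "CentralityProfile"))
    if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau > 1)
        stop("tau must lie in (0, 1]")
    v <- profile@centrality
    sel <- v[v >= tau]
    names(sort(sel, decreasing = TRUE))
}

#' Full topology report for a network
#'
#' Bundles node strength, Barrat clustering, the hierarchy diagnostic
#' and the scale-free diagnostic (see
#' \code{\link{scaleFreeDiagnostic}}) into one object.
#'
#' @param net a \code{\linkS4class{GeneNetwork}}.
#' @param nBoot bootstrap replicates for the power-law fit.
#' @param seed seed for the bootstrap.
#' @return a \code{\linkS4class{TopologyReport}}.
#' @export
topologyReport <- function(net, nBoot = 100, seed = 1) {
    s <- nodeStrength(net)
    ci <- weightedClustering(net)
    hier <- hierarchyDiagnostic(net)
    sf <- scaleFreeDiagnostic(s, nBoot = nBoot, seed = seed)
    new("TopologyReport", strength = s, clustering = ci,
        hierarchy = hier, scaleFree = sf)
}
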