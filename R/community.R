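#' Weighted modularity coefficient
#'
#' \deqn{Q = \frac{1}{2W} \sum_{ij} \left(w_{ij} -
#'   \frac{s_i s_j}{2W}\right) \delta(c_i, c_j)}
#' where \eqn{W} is the total edge weight and \eqn{s_i} the node
#' strengths: the within-cluster weight minus its expectation if genes
#' associated at random proportionally to their strengths. \eqn{Q} is
#' invariant to cluster relabeling and to uniform weight rescaling and
#' lies in \eqn{[-1/2, 1]}.
#'
#' @param net a \code{\linkS4class{GeneNetwork}} with positive total
#'   weight.
#' @param membership a \code{\linkS4class{Partition}} or a vector of
#'   cluster ids covering every gene of the network.
#' @return the modularity coefficient Q.
#' @export
modularityCoefficient <- function(net, membership) {
    stopifnot(is(net, "GeneNetwork"))
    if (is(membership, "Partition"))
        membership <- membership@membership
    A <- net@adjacency
    p <- nrow(A)
    if (length(membership) != p)
        stop("membership must cover every gene of the network")
    if (!is.null(names(membership))) {
        if (!setequal(names(membership), rownames(A)))
            stop("membership names do not match network genes")
        membership <- membership[rownames(A)]
    }
    if (anyNA(membership))
        stop("membership must assign every gene")
    W2 <- sum(A)           # 2W
    if (W2 <= 0)
        stop("empty network: total edge weight is zero")
    s <- rowSums(A)
    q <- 0
    for (cl in unique(membership)) {
        idx <- membership == cl
        q <- q + sum(A[idx, idx]) / W2 - (sum(s[idx]) / W2)^2
    }
    q
}

#' Modularity-based community detection
#'
#' Weighted Louvain-style greedy modularity maximization (multi-level
#' aggregation), seeded so results are reproducible. Isolated genes end
#' up as singleton clusters. The returned partition is guaranteed to
#' score at least as well as the trivial one-cluster and all-singletons
#' baselines (whichever of the three scores best is returned).
#'
#' @param net a \code{\linkS4class{GeneNetwork}} with positive total
#'   weight.
#' @param seed integer seed (default 1).
#' @return a \code{\linkS4class{Partition}} carrying its modularity Q.
#' @export
detectCommunities <- function(net, seed = 1) {
    stopifnot(is(net, "GeneNetwork"))
    if (sum(net@adjacency) <= 0)
        stop("empty network: total edge weight is zero")
    g <- .asIgraph(net)
    cl <- .withSeed(seed, igraph::cluster_louvain(g,
        weights = igraph::E(g)$weight))
    memb <- as.integer(igraph::membership(cl))
    names(memb) <- rownames(net@adjacency)
    qLouvain <- modularityCoefficient(net, memb)
    # baselines: one cluster (Q = 0) and all singletons
    single <- seq_along(memb)
    names(single) <- names(memb)
    one <- rep(1L, length(memb))
    names(one) <- names(memb)
    cands <- list(louvain = list(m = memb, q = qLouvain),
        one_cluster = list(m = one, q = 0),
        singletons = list(m = single,
            q = modularityCoefficient(net, single)))
    best <- cands[[which.max(vapply(cands, `[[`, numeric(1), "q"))]]
    new("Partition", membership = best$m, Q = best$q,
        algorithm = "louvain", seed = as.integer(seed))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between cluster assignments; 1 for
#' identical partitions (up to relabeling), ~0 for independent ones.
#'
#' @param a,b \code{\linkS4class{Partition}} objects or assignment
#'   vectors over the same genes.
#' @return the adjusted Rand index.
#' @export
adjustedRand <- function(a, b) {
    if (is(a, "Partition")) a <- a@membership
    if (is(b, "Partition")) b <- b@membership
    if (!is.null(names(a)) && !is.null(names(b))) {
        if (!setequal(names(a), names(b)))
            stop(sprintf("partitions cover different genes: %s",
                paste(utils::head(c(setdiff(names(a), names(b)),
                    setdiff(names(b), names(a))), 5), collapse = ", ")))
        b <- b[names(a)]
    }
    if (length(a) != length(b))
        stop("partitions must cover the same genes")
    mclust::adjustedRandIndex(a, b)
}

#' Cluster flow across an ordered series of partitions
#'
#' For each consecutive pair of partitions (e.g. treatment levels),
#' tabulates cluster co-membership and computes the adjusted Rand
#' index, quantifying how gene cluster membership rewires along the
#' series.
#'
#' @param partitions ordered list of \code{\linkS4class{Partition}}
#'   objects (or assignment vectors) over the same gene set.
#' @param labels optional labels of the series (defaults to list names
#'   or indices).
#' @return list of elements \code{from}, \code{to}, \code{table}
#'   (cluster contingency table) and \code{ari}.
#' @export
clusterCrosstab <- function(partitions, labels = NULL) {
    if (length(partitions) < 2)
        stop("need at least two partitions")
    memb <- lapply(partitions, function(p)
        if (is(p, "Partition")) p@membership else p)
    genes <- names(memb[[1]])
    for (i in seq_along(memb)[-1]) {
        if (!is.null(genes) && !is.null(names(memb[[i]]))) {
            miss <- c(setdiff(genes, names(memb[[i]])),
                setdiff(names(memb[[i]]), genes))
            if (length(miss))
                stop(sprintf("partitions cover different genes: %s",
                    paste(utils::head(miss, 5), collapse = ", ")))
            memb[[i]] <- memb[[i]][genes]
        } else if (length(memb[[i]]) != length(memb[[1]])) {
            stop("partitions must cover the same genes")
        }
    }
    if (is.null(labels))
        labels <- if (!is.null(names(partitions))) names(partitions)
            else as.character(seq_along(partitions))
    lapply(seq_len(length(memb) - 1), function(i) {
        list(from = labels[i], to = labels[i + 1],
            table = table(from = memb[[i]], to = memb[[i + 1]]),
            ari = mclust::adjustedRandIndex(memb[[i]], memb[[i + 1]]))
    })
}
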