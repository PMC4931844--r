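# Ravasz-Barabasi-Vicsek deterministic hierarchical graph: a 5-clique
# replicated recursively, peripheral nodes of the four replicas wired to
# the central hub; clustering decreases with degree across levels.
.nestedCliques <- function(levels) {
    build <- function(L) {
        if (L == 1)
            return(list(n = 5L, edges = t(utils::combn(5L, 2L)),
                center = 1L, periph = 2:5))
        sub <- build(L - 1)
        edges <- do.call(rbind, lapply(0:4, function(cc)
            sub$edges + cc * sub$n))
        periph <- unlist(lapply(1:4, function(cc) sub$periph + cc * sub$n))
        edges <- rbind(edges, cbind(periph, sub$center))
        list(n = 5L * sub$n, edges = edges, center = sub$center,
            periph = periph)
    }
    build(levels)
}

#' Generate reference networks with known topology
#'
#' Fixture generators for the topology diagnostics: a
#' preferential-attachment graph (\code{"scale_free"}, \code{param} =
#' edges added per node), an Erdős–Rényi graph (\code{"random"},
#' \code{param} = edge probability), two equal disconnected cliques
#' (\code{"two_cliques"}), or a deterministic nested-clique hierarchy
#' (\code{"nested_cliques"}, \code{param} = recursion depth; 5^param
#' nodes, \code{nNodes} ignored beyond validation). All edges have unit
#' weight; output is deterministic given the seed.
#'
#' @param kind one of \code{"scale_free"}, \code{"random"},
#'   \code{"two_cliques"}, \code{"nested_cliques"}.
#' @param nNodes number of nodes (>= 3).
#' @param param kind-specific parameter (see above).
#' @param seed integer seed (used by the stochastic kinds).
#' @return a \code{\linkS4class{GeneNetwork}} with provenance
#'   \code{"reference"}.
#' @export
generateReferenceNetwork <- function(kind = c("scale_free", "random",
    "two_cliques", "nested_cliques"), nNodes, param = 1, seed = 1) {
    kind <- match.arg(kind)
    if (!is.numeric(nNodes) || length(nNodes) != 1L || nNodes < 3)
        stop("nNodes must be a single integer >= 3")
    nNodes <- as.integer(nNodes)
    g <- switch(kind,
        scale_free = .withSeed(seed, igraph::sample_pa(nNodes,
            m = max(1, round(param)), directed = FALSE)),
        random = .withSeed(seed, igraph::sample_gnp(nNodes, param)),
        two_cliques = {
            h <- nNodes %/% 2L
            igraph::disjoint_union(igraph::make_full_graph(h),
                igraph::make_full_graph(nNodes - h))
        },
        nested_cliques = {
            rb <- .nestedCliques(max(1L, as.integer(round(param))))
            igraph::graph_from_edgelist(rb$edges, directed = FALSE)
        })
    A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = TRUE))
    A[A > 0] <- 1
    storage.mode(A) <- "double"
    rownames(A) <- colnames(A) <- sprintf("n%04d", seq_len(nrow(A)))
    geneNetwork(A, provenance = "reference")
}
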