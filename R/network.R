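#' Construct a GeneNetwork from an adjacency matrix
#'
#' @param adjacency symmetric non-negative numeric matrix with zero
#'   diagonal; zero entries mean "no edge". Row names are gene ids
#'   (generated if absent).
#' @param provenance character tag (default \code{"cmi"}).
#' @param dpiEpsilon DPI tolerance used to produce the network, or
#'   \code{NA} if it was not pruned.
#' @return a \code{\linkS4class{GeneNetwork}}.
#' @export
geneNetwork <- function(adjacency, provenance = "cmi", dpiEpsilon = NA_real_) {
    if (is.null(rownames(adjacency)))
        rownames(adjacency) <- colnames(adjacency) <-
            sprintf("g%03d", seq_len(nrow(adjacency)))
    new("GeneNetwork", adjacency = adjacency, provenance = provenance,
        dpiEpsilon = as.numeric(dpiEpsilon))
}

# internal: igraph view of a GeneNetwork (weighted, undirected)
.asIgraph <- function(net) {
    igraph::graph_from_adjacency_matrix(net@adjacency, mode = "undirected",
        weighted = TRUE, diag = FALSE)
}

#' Summary statistics of a gene network
#'
#' @param net a \code{\linkS4class{GeneNetwork}}.
#' @return list with \code{edges} (edge count), \code{meanDegree},
#'   \code{meanWeight} (mean positive edge weight; 0 if edgeless) and
#'   \code{components} (connected-component count, isolated nodes
#'   included).
#' @export
networkSummary <- function(net) {
    stopifnot(is(net, "GeneNetwork"))
    a <- net@adjacency
    up <- a[upper.tri(a)]
    ne <- sum(up > 0)
    deg <- rowSums(a > 0)
    comp <- igraph::components(.asIgraph(net))$no
    list(edges = ne, meanDegree = mean(deg),
        meanWeight = if (ne > 0) mean(up[up > 0]) else 0,
        components = comp)
}
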