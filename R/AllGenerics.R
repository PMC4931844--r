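#' Accessors for crnet containers
#'
#' Small accessor generics: \code{mim} returns the similarity matrix of
#' a \code{MIMatrix}, \code{estimator} its tag; \code{adjacency},
#' \code{provenance} and \code{dpiEpsilon} read a \code{GeneNetwork};
#' \code{geneNames} works on both; \code{clusterAssignments},
#' \code{modularityQ} and \code{nClusters} read a \code{Partition};
#' \code{centralities} and \code{dominantEigenvalue} read a
#' \code{CentralityProfile}; \code{predictiveScores}, \code{explainedXvar}
#' and \code{permutationP} read an \code{OplsdaResult}.
#'
#' @param x an object of the corresponding class.
#' @return the slot contents (matrices, named vectors, or scalars).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("mim", function(x) standardGeneric("mim"))
#' @rdname accessors
#' @export
setGeneric("estimator", function(x) standardGeneric("estimator"))
#' @rdname accessors
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("dpiEpsilon", function(x) standardGeneric("dpiEpsilon"))
#' @rdname accessors
#' @export
setGeneric("geneNames", function(x) standardGeneric("geneNames"))
#' @rdname accessors
#' @export
setGeneric("clusterAssignments", function(x) standardGeneric("clusterAssignments"))
#' @rdname accessors
#' @export
setGeneric("modularityQ", function(x) standardGeneric("modularityQ"))
#' @rdname accessors
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))
#' @rdname accessors
#' @export
setGeneric("centralities", function(x) standardGeneric("centralities"))
#' @rdname accessors
#' @export
setGeneric("dominantEigenvalue", function(x) standardGeneric("dominantEigenvalue"))
#' @rdname accessors
#' @export
setGeneric("predictiveScores", function(x) standardGeneric("predictiveScores"))
#' @rdname accessors
#' @export
setGeneric("explainedXvar", function(x) standardGeneric("explainedXvar"))
#' @rdname accessors
#' @export
setGeneric("permutationP", function(x) standardGeneric("permutationP"))

#' @rdname accessors
setMethod("mim", "MIMatrix", function(x) x@mim)
#' @rdname accessors
setMethod("estimator", "MIMatrix", function(x) x@estimator)
#' @rdname accessors
setMethod("geneNames", "MIMatrix", function(x) rownames(x@mim))
#' @rdname accessors
setMethod("adjacency", "GeneNetwork", function(x) x@adjacency)
#' @rdname accessors
setMethod("provenance", "GeneNetwork", function(x) x@provenance)
#' @rdname accessors
setMethod("dpiEpsilon", "GeneNetwork", function(x) x@dpiEpsilon)
#' @rdname accessors
setMethod("geneNames", "GeneNetwork", function(x) rownames(x@adjacency))
#' @rdname accessors
setMethod("clusterAssignments", "Partition", function(x) x@membership)
#' @rdname accessors
setMethod("modularityQ", "Partition", function(x) x@Q)
#' @rdname accessors
setMethod("nClusters", "Partition",
    function(x) length(unique(x@membership)))
#' @rdname accessors
setMethod("centralities", "CentralityProfile", function(x) x@centrality)
#' @rdname accessors
setMethod("dominantEigenvalue", "CentralityProfile", function(x) x@eigenvalue)
#' @rdname accessors
setMethod("predictiveScores", "OplsdaResult", function(x) x@scores)
#' @rdname accessors
setMethod("explainedXvar", "OplsdaResult", function(x) x@xvar)
#' @rdname accessors
setMethod("permutationP", "OplsdaResult", function(x) x@permP)

setMethod("show", "MIMatrix", function(object) {
    p <- nrow(object@mim)
    cat(sprintf("MIMatrix: %d genes, estimator = %s\n", p, object@estimator))
    off <- object@mim[upper.tri(object@mim)]
    if (length(off))
        cat(sprintf("  pairwise similarity: mean %.4f, max %.4f (nats)\n",
            mean(off), max(off)))
})

setMethod("show", "GeneNetwork", function(object) {
    a <- object@adjacency
    ne <- sum(a[upper.tri(a)] > 0)
    cat(sprintf("GeneNetwork (%s): %d genes, %d edges", object@provenance,
        nrow(a), ne))
    if (!is.na(object@dpiEpsilon))
        cat(sprintf(", DPI epsilon = %g", object@dpiEpsilon))
    cat("\n")
})

setMethod("show", "Partition", function(object) {
    cat(sprintf("Partition (%s): %d genes in %d clusters, Q = %.4f\n",
        object@algorithm, length(object@membership),
        nClusters(object), object@Q))
})

setMethod("show", "CentralityProfile", function(object) {
    cat(sprintf(
        "CentralityProfile: %d genes, dominant eigenvalue %.4f, component size %d\n",
        length(object@centrality), object@eigenvalue,
        length(object@component)))
})

setMethod("show", "TopologyReport", function(object) {
    cat(sprintf("TopologyReport: %d genes\n", length(object@strength)))
    cat(sprintf("  hierarchy: %s (rho = %.3f, p = %.3g)\n",
        object@hierarchy$verdict,
        ifelse(is.na(object@hierarchy$rho), NA, object@hierarchy$rho),
        object@hierarchy$p))
    cat(sprintf("  scale-free: %s (R2 = %.3f, alpha = %.2f, KS p = %.3f)\n",
        object@scaleFree$verdict, object@scaleFree$r2,
        object@scaleFree$alpha, object@scaleFree$ksP))
})

setMethod("show", "OplsdaResult", function(object) {
    cat(sprintf(
        "OplsdaResult: %d samples, %d predictive components, %d orthogonal removed\n",
        nrow(object@scores), ncol(object@scores), object@nOrtho))
    cat(sprintf("  Xvar = %.1f%%", object@xvar))
    if (!is.na(object@permP))
        cat(sprintf(", permutation p = %.4g (%d permutations)",
            object@permP, object@nPermutations))
    cat("\n")
})

setMethod("show", "ComparisonReport", function(object) {
    cat("ComparisonReport\n")
    print(object@summaryTable)
    cat(sprintf("  hash: %s\n", object@hash))
})

setMethod("show", "SyntheticSpec", function(object) {
    cat(sprintf(
        "SyntheticSpec: %d genes in %d clusters, %d levels (%s), seed %d\n",
        object@nGenes, length(object@clusterSizes),
        length(object@treatmentLevels),
        paste(object@treatmentLevels, collapse = ", "), object@seed))
})
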