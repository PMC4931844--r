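#' @import methods
NULL

.checkSquareSym <- function(m, what, tol = 1e-10) {
    msgs <- character(0)
    if (!is.matrix(m) || !is.numeric(m))
        return(sprintf("%s must be a numeric matrix", what))
    if (nrow(m) != ncol(m))
        msgs <- c(msgs, sprintf("%s must be square", what))
    else {
        if (any(abs(m - t(m)) > tol))
            msgs <- c(msgs, sprintf("%s must be symmetric", what))
        if (any(m < -tol))
            msgs <- c(msgs, sprintf("%s must be non-negative", what))
        if (any(abs(diag(m)) > tol))
            msgs <- c(msgs, sprintf("%s must have a zero diagonal", what))
        if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
            msgs <- c(msgs, sprintf("%s needs unique row/column names", what))
    }
    if (length(msgs)) msgs else TRUE
}

#' Symmetric gene-by-gene similarity matrix
#'
#' Container for a pairwise dependency matrix between genes: either
#' Miller-Madow mutual information in nats (\code{estimator =
#' "miller_madow"}) or the Gaussian mutual-information proxy
#' \eqn{-\frac12 \log(1-\rho^2)} of Spearman correlations
#' (\code{estimator = "spearman_gaussian"}). The diagonal is zero by
#' convention and all entries are non-negative.
#'
#' @slot mim symmetric numeric matrix with unique gene names.
#' @slot estimator character tag of the estimator that produced it.
#' @export
setClass("MIMatrix",
    representation(mim = "matrix", estimator = "character"),
    validity = function(object) {
        msgs <- .checkSquareSym(object@mim, "mim")
        if (!isTRUE(msgs)) return(msgs)
        if (!object@estimator %in% c("miller_madow", "spearman_gaussian"))
            return("estimator must be 'miller_madow' or 'spearman_gaussian'")
        TRUE
    })

#' Weighted undirected gene network
#'
#' A gene network after pruning: symmetric non-negative adjacency with
#' zero meaning "no edge". Surviving edges keep the similarity value
#' they had before pruning.
#'
#' @slot adjacency symmetric numeric matrix, zero diagonal.
#' @slot provenance character, e.g. \code{"cmi"}, \code{"spearman"} or
#'   \code{"reference"}.
#' @slot dpiEpsilon numeric tolerance used at DPI pruning (\code{NA} if
#'   the network was not pruned).
#' @export
setClass("GeneNetwork",
    representation(adjacency = "matrix", provenance = "character",
        dpiEpsilon = "numeric"),
    validity = function(object) {
        msgs <- .checkSquareSym(object@adjacency, "adjacency")
        if (!isTRUE(msgs)) return(msgs)
        if (length(object@dpiEpsilon) != 1L)
            return("dpiEpsilon must be a single number (or NA)")
        if (!is.na(object@dpiEpsilon) && object@dpiEpsilon < 0)
            return("dpiEpsilon must be >= 0")
        TRUE
    })

#' Modularity-based partition of a gene network
#'
#' @slot membership named integer vector, one cluster id per gene.
#' @slot Q modularity coefficient of the partition.
#' @slot algorithm character tag of the algorithm that produced it.
#' @slot seed integer seed used by the algorithm.
#' @export
setClass("Partition",
    representation(membership = "integer", Q = "numeric",
        algorithm = "character", seed = "integer"),
    validity = function(object) {
        if (is.null(names(object@membership)))
            return("membership must be named by gene")
        if (anyNA(object@membership))
            return("every gene must be assigned to exactly one cluster")
        if (length(object@Q) != 1L || is.na(object@Q))
            return("Q must be a single number")
        if (object@Q < -0.5 - 1e-9 || object@Q > 1 + 1e-9)
            return("Q must lie in [-0.5, 1]")
        TRUE
    })

#' Eigenvector-centrality profile of a network
#'
#' Entries of the dominant eigenvector of the (symmetric, non-negative)
#' adjacency, rescaled so the maximum is 1. For a disconnected graph the
#' profile is computed on the component with the largest dominant
#' eigenvalue; genes outside it get 0.
#'
#' @slot centrality named numeric vector in [0, 1]; max is 1.
#' @slot eigenvalue dominant eigenvalue of the component used.
#' @slot component integer ids of the genes in the component used.
#' @export
setClass("CentralityProfile",
    representation(centrality = "numeric", eigenvalue = "numeric",
        component = "integer"),
    validity = function(object) {
        v <- object@centrality
        if (is.null(names(v))) return("centrality must be named by gene")
        if (any(v < -1e-12 | v > 1 + 1e-12))
            return("centrality values must lie in [0, 1]")
        if (abs(max(v) - 1) > 1e-9)
            return("at least one centrality value must equal 1")
        TRUE
    })

#' Node-level and global topology report
#'
#' @slot strength named numeric vector of node strengths (row sums of
#'   the similarity matrix restricted to surviving edges).
#' @slot clustering named numeric vector of Barrat weighted clustering
#'   coefficients in [0, 1].
#' @slot hierarchy list with elements \code{rho}, \code{p},
#'   \code{verdict} ("yes"/"no"/"inconclusive").
#' @slot scaleFree list with elements \code{r2}, \code{alpha},
#'   \code{xmin}, \code{ks}, \code{ksP}, \code{verdict}.
#' @export
setClass("TopologyReport",
    representation(strength = "numeric", clustering = "numeric",
        hierarchy = "list", scaleFree = "list"))

#' O-PLS-DA fit summary
#'
#' @slot scores samples-by-components matrix of predictive scores.
#' @slot nOrtho number of orthogonal components removed.
#' @slot xvar percent of (scaled) predictor variance captured by the
#'   predictive components.
#' @slot permP permutation p-value (\code{NA} until computed).
#' @slot nPermutations number of label permutations behind \code{permP}.
#' @slot seed integer seed.
#' @export
setClass("OplsdaResult",
    representation(scores = "matrix", nOrtho = "integer", xvar = "numeric",
        permP = "numeric", nPermutations = "integer", seed = "integer"),
    validity = function(object) {
        if (object@xvar < -1e-9 || object@xvar > 100 + 1e-9)
            return("xvar must lie in [0, 100]")
        if (!is.na(object@permP)) {
            if (object@permP <= 0 || object@permP > 1)
                return("permutation p-value must lie in (0, 1]")
            lb <- 1 / (object@nPermutations + 1)
            if (object@permP < lb - 1e-12)
                return("permutation p-value below its attainable minimum")
        }
        TRUE
    })

#' Cross-treatment, cross-estimator comparison report
#'
#' @slot summaryTable data.frame with one row per treatment-by-estimator
#'   network: modularity Q, number of clusters, edge count, mean degree,
#'   central genes (comma-separated).
#' @slot centrality list (one matrix per estimator) of gene-by-level
#'   eigenvector centralities on the max-1 scale, NA where a gene sits
#'   outside the dominant component.
#' @slot trends list (one data.frame per estimator) of per-gene
#'   centrality trend statistics across ordered levels.
#' @slot flows list (one element per estimator) of consecutive-level
#'   cluster cross-tabulations with adjusted Rand indices.
#' @slot centralOverlap data.frame of per-treatment central-gene overlap
#'   between estimators.
#' @slot config list: the configuration the report was produced from.
#' @slot hash md5 of the canonical JSON serialization of the report.
#' @export
setClass("ComparisonReport",
    representation(summaryTable = "data.frame", centrality = "list",
        trends = "list", flows = "list", centralOverlap = "data.frame",
        config = "list", hash = "character"))

#' Specification of a synthetic graded-treatment expression study
#'
#' Parameters of the latent-factor generative model: genes are grouped
#' into clusters, each cluster is driven by one latent factor per
#' treatment level, and gene expression is a linear (or, for planted
#' non-monotone genes, quadratic) function of the cluster factor plus
#' Gaussian noise, exponentiated onto a positive normalized-count-like
#' scale.
#'
#' @slot nGenes total number of genes.
#' @slot clusterSizes integer sizes of the planted clusters
#'   (sums to \code{nGenes}).
#' @slot treatmentLevels ordered character labels of treatment levels.
#' @slot samplesPerLevel integer samples per level (same length).
#' @slot rewireFraction fraction of genes reassigned to another cluster
#'   at each level, relative to the first level (same length, in [0,1]).
#' @slot hubGenes integer gene indices acting as hubs.
#' @slot hubMultiplier loading multiplier for hub genes.
#' @slot crossLoading hub loading on ring-neighbour cluster factors.
#' @slot factorCor exchangeable correlation between cluster factors.
#' @slot nonmonotoneFraction fraction of genes per cluster whose link to
#'   the factor is quadratic (U-shaped against linear cluster-mates).
#' @slot factorTrend magnitude of the graded per-cluster shift of the
#'   factor means along the treatment gradient (the "state shift" the
#'   classification stage detects).
#' @slot deFraction fraction of genes with a graded treatment mean
#'   shift on the log scale (differential expression along the
#'   gradient).
#' @slot deMagnitude maximum absolute log-scale shift, reached at the
#'   last treatment level.
#' @slot noiseSd standard deviation of additive noise on the log scale.
#' @slot seed integer seed.
#' @export
setClass("SyntheticSpec",
    representation(nGenes = "integer", clusterSizes = "integer",
        treatmentLevels = "character", samplesPerLevel = "integer",
        rewireFraction = "numeric", hubGenes = "integer",
        hubMultiplier = "numeric", crossLoading = "numeric",
        factorCor = "numeric", nonmonotoneFraction = "numeric",
        factorTrend = "numeric",
        deFraction = "numeric", deMagnitude = "numeric",
        noiseSd = "numeric", seed = "integer"),
    validity = function(object) {
        if (sum(object@clusterSizes) != object@nGenes)
            return("clusterSizes: sum(clusterSizes) must equal nGenes")
        if (any(object@clusterSizes < 1L))
            return("clusterSizes: every cluster needs at least one gene")
        k <- length(object@treatmentLevels)
        if (length(object@samplesPerLevel) != k)
            return("samplesPerLevel: length must match treatmentLevels")
        if (length(object@rewireFraction) != k)
            return("rewireFraction: length must match treatmentLevels")
        if (any(object@samplesPerLevel < 1L))
            return("samplesPerLevel: every level needs samples")
        fr <- c(object@rewireFraction, object@nonmonotoneFraction,
            object@factorCor, object@deFraction)
        if (any(fr < 0 | fr > 1))
            return("rewireFraction/nonmonotoneFraction/factorCor: fractions must lie in [0,1]")
        if (any(object@rewireFraction > 0) && length(object@clusterSizes) < 2L)
            return("rewireFraction: rewiring needs at least two clusters")
        if (!length(object@hubMultiplier) %in% c(1L, k))
            return("hubMultiplier: length must be 1 or the number of levels")
        if (any(object@hubMultiplier <= 0))
            return("hubMultiplier: must be > 0")
        if (object@noiseSd <= 0)
            return("noiseSd: must be > 0")
        if (object@factorTrend < 0 || object@deMagnitude < 0)
            return("factorTrend/deMagnitude: must be >= 0")
        if (length(object@hubGenes) &&
            (any(object@hubGenes < 1L) || any(object@hubGenes > object@nGenes)))
            return("hubGenes: indices must lie in 1..nGenes")
        TRUE
    })
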