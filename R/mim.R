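#' @importFrom SummarizedExperiment assay colData
NULL

# Coerce a genes x samples matrix or SummarizedExperiment (optionally
# subset to one treatment) into a named numeric matrix.
.exprMatrix <- function(x, treatment = NULL) {
    if (is(x, "SummarizedExperiment")) {
        m <- assay(x)
        if (!is.null(treatment)) {
            tr <- colData(x)$treatment
            if (is.null(tr))
                stop("SummarizedExperiment has no 'treatment' column")
            keep <- tr == treatment
            if (!any(keep))
                stop(sprintf("no samples with treatment '%s'", treatment))
            m <- m[, keep, drop = FALSE]
        }
        x <- m
    }
    if (!is.matrix(x) || !is.numeric(x))
        stop("expression input must be a numeric matrix or SummarizedExperiment")
    if (anyNA(x))
        stop("expression matrix must not contain missing values")
    if (is.null(rownames(x)))
        rownames(x) <- sprintf("g%03d", seq_len(nrow(x)))
    if (anyDuplicated(rownames(x)))
        stop("gene ids must be unique")
    x
}

#' Pairwise Miller-Madow mutual-information matrix
#'
#' Discretizes every gene with a common bin count and estimates
#' Miller-Madow mutual information for all unordered gene pairs; this
#' is the first step of the two-step network inference (the second is
#' \code{\link{aracne}} pruning).
#'
#' @param x genes-by-samples numeric matrix, or a
#'   \code{SummarizedExperiment} with an expression assay and a
#'   \code{treatment} column in \code{colData}.
#' @param treatment optional treatment label: restrict to those samples
#'   (requires a \code{SummarizedExperiment}).
#' @param bins bins per gene; \code{NULL} (default) uses
#'   \code{\link{defaultBins}} of the sample count.
#' @param scheme binning scheme, see \code{\link{discretize}}.
#' @param clamp clamp negative MI estimates to 0 (default \code{TRUE}).
#' @param verbose log progress every 10\% of pairs.
#' @return a \code{\linkS4class{MIMatrix}} (symmetric, zero diagonal,
#'   estimator \code{"miller_madow"}).
#' @export
buildMIM <- function(x, treatment = NULL, bins = NULL,
    scheme = c("equal_frequency", "equal_width"),
    clamp = TRUE, verbose = FALSE) {
    scheme <- match.arg(scheme)
    x <- .exprMatrix(x, treatment)
    p <- nrow(x)
    n <- ncol(x)
    if (p < 2)
        stop("need at least two genes")
    if (n < 3)
        stop("need at least three samples for inference")
    B <- if (is.null(bins)) defaultBins(n) else as.integer(bins)

    D <- matrix(0L, p, n)
    for (g in seq_len(p))
        D[g, ] <- discretize(x[g, ], B, scheme)

    # per-gene marginal entropies, reused across all pairs
    Hm <- numeric(p)
    for (g in seq_len(p)) {
        cg <- tabulate(D[g, ] + 1L, B)
        Hm[g] <- .hmm(cg[cg > 0], n)
    }

    M <- matrix(0, p, p, dimnames = list(rownames(x), rownames(x)))
    npairs <- p * (p - 1) / 2
    step <- max(1, floor(npairs / 10))
    done <- 0
    BB <- B * B
    for (i in seq_len(p - 1)) {
        di <- D[i, ] * B
        for (j in (i + 1):p) {
            cxy <- tabulate(di + D[j, ] + 1L, BB)
            mi <- Hm[i] + Hm[j] - .hmm(cxy[cxy > 0], n)
            if (clamp && mi < 0) mi <- 0
            M[i, j] <- M[j, i] <- mi
            done <- done + 1
            if (verbose && done %% step == 0)
                message(sprintf("buildMIM: %d/%d pairs (%.0f%%)", done,
                    npairs, 100 * done / npairs))
        }
    }
    new("MIMatrix", mim = M, estimator = "miller_madow")
}
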