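#' Spearman-correlation similarity matrix
#'
#' Rank-correlation counterpart of \code{\link{buildMIM}}: pairwise
#' Spearman \eqn{\rho} (average ranks for ties) mapped onto the
#' Gaussian mutual-information scale \eqn{-\frac12\log(1-\rho^2)}
#' (nats), so correlation- and MI-based networks are comparable under a
#' common pruning rule. \eqn{|\rho| = 1} would map to infinity; those
#' entries are capped at the largest finite similarity in the matrix
#' plus one, which preserves rank order.
#'
#' @inheritParams buildMIM
#' @return a \code{\linkS4class{MIMatrix}} with estimator
#'   \code{"spearman_gaussian"}.
#' @export
spearmanSimilarity <- function(x, treatment = NULL) {
    x <- .exprMatrix(x, treatment)
    if (ncol(x) < 4)
        stop("need at least four samples")
    sds <- apply(x, 1, stats::sd)
    const <- sds == 0
    rho <- suppressWarnings(stats::cor(t(x), method = "spearman"))
    if (any(const)) {
        warning(sprintf("%d constant gene(s): similarities set to 0 (%s)",
            sum(const), paste(utils::head(rownames(x)[const], 5),
                collapse = ", ")))
        rho[const, ] <- 0
        rho[, const] <- 0
    }
    sim <- -0.5 * log1p(-rho^2)
    diag(sim) <- 0
    inf <- !is.finite(sim)
    if (any(inf)) {
        cap <- max(sim[!inf], 0) + 1
        sim[inf] <- cap
    }
    sim[sim < 0] <- 0  # guard tiny negatives from log1p rounding
    sim <- (sim + t(sim)) / 2
    diag(sim) <- 0
    new("MIMatrix", mim = sim, estimator = "spearman_gaussian")
}
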