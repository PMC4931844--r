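#' Miller-Madow entropy of a count vector
#'
#' Plug-in (empirical) entropy with the Miller-Madow asymptotic bias
#' correction: \eqn{\hat H_{MM} = \hat H_{emp} + (\hat m - 1)/(2n)}
#' where \eqn{\hat m} is the number of non-empty cells and \eqn{n} the
#' total count. The plug-in estimator is downward biased by roughly
#' \eqn{(m-1)/(2n)}; adding the term back matters at the small sample
#' sizes of per-treatment networks.
#'
#' @param counts non-negative integer cell counts of a contingency
#'   table (any shape, flattened).
#' @return entropy in nats.
#' @examples
#' millerMadowEntropy(c(2, 2))  # log(2) + 1/8
#' @export
millerMadowEntropy <- function(counts) {
    if (anyNA(counts) || any(counts < 0))
        stop("counts must be non-negative")
    n <- sum(counts)
    if (n < 1)
        stop("empty distribution")
    .hmm(counts[counts > 0], n)
}

# internal fast path: positive counts only, n precomputed
.hmm <- function(pos, n) {
    p <- pos / n
    -sum(p * log(p)) + (length(pos) - 1) / (2 * n)
}

#' Miller-Madow mutual information between two discretized vectors
#'
#' \eqn{\hat I = \hat H_{MM}(X) + \hat H_{MM}(Y) - \hat H_{MM}(X,Y)}
#' from the one- and two-dimensional contingency tables of the bin
#' indices. The Miller-Madow corrections do not cancel, so the estimate
#' can be negative; negative values are clamped to 0 by default because
#' network weights must be non-negative (set \code{clamp = FALSE} to
#' recover the raw value).
#'
#' @param xb,yb integer bin vectors of equal length.
#' @param clamp clamp negative estimates to 0 (default \code{TRUE}).
#' @return mutual information in nats.
#' @examples
#' miMillerMadow(c(0, 0, 1, 1), c(0, 0, 1, 1))  # log(2) + 1/8
#' miMillerMadow(c(0, 0, 1, 1), c(0, 1, 0, 1))  # 0 (clamped)
#' @export
miMillerMadow <- function(xb, yb, clamp = TRUE) {
    if (length(xb) != length(yb))
        stop("xb and yb must have the same length")
    n <- length(xb)
    if (n < 2)
        stop("need at least two samples")
    xb <- as.integer(xb) - min(as.integer(xb))
    yb <- as.integer(yb) - min(as.integer(yb))
    bx <- max(xb) + 1L
    by <- max(yb) + 1L
    cx <- tabulate(xb + 1L, bx)
    cy <- tabulate(yb + 1L, by)
    cxy <- tabulate(xb * by + yb + 1L, bx * by)
    i <- .hmm(cx[cx > 0], n) + .hmm(cy[cy > 0], n) - .hmm(cxy[cxy > 0], n)
    if (clamp) max(i, 0) else i
}
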