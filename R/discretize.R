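#' Discretize a numeric vector into bins
#'
#' Equal-frequency binning assigns near-equal occupancy by rank, with
#' ties broken by original position, so every gene contributes a
#' comparable marginal distribution to the entropy estimator.
#' Equal-width binning splits \eqn{[\min(x), \max(x)]} into \code{B}
#' equal intervals; a constant vector collapses into bin 0.
#'
#' @param x numeric vector.
#' @param B number of bins (>= 2).
#' @param scheme \code{"equal_frequency"} (default) or
#'   \code{"equal_width"}.
#' @return integer vector of bin indices in \code{0:(B-1)}.
#' @examples
#' discretize(1:6, 2)                     # 0 0 0 1 1 1
#' discretize(c(5, 5, 5, 5), 3, "equal_width")  # all 0
#' @export
discretize <- function(x, B, scheme = c("equal_frequency", "equal_width")) {
    scheme <- match.arg(scheme)
    if (!is.numeric(B) || length(B) != 1L || B < 2)
        stop("B must be a single integer >= 2")
    B <- as.integer(B)
    if (anyNA(x))
        stop("x must not contain missing values")
    n <- length(x)
    if (scheme == "equal_frequency") {
        if (n < B)
            stop("equal_frequency binning needs length(x) >= B")
        r <- rank(x, ties.method = "first")
        return(as.integer(((r - 1L) * B) %/% n))
    }
    rng <- range(x)
    if (rng[1] == rng[2])
        return(integer(n))  # constant vector: everything in bin 0
    idx <- floor((x - rng[1]) / (rng[2] - rng[1]) * B)
    as.integer(pmin(idx, B - 1L))
}

#' Default bin count for mutual-information estimation
#'
#' The square-root heuristic \eqn{B = \lfloor\sqrt{n}\rfloor}, floored
#' at 2, which balances resolution against contingency-table sparsity
#' on the small per-treatment sample sizes typical of this design.
#'
#' @param n number of samples.
#' @return integer bin count.
#' @export
defaultBins <- function(n) max(2L, as.integer(floor(sqrt(n))))
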