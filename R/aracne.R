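#' ARACNE pruning by the data-processing inequality
#'
#' Second step of the two-step inference: every pair initially carries
#' its similarity as edge weight, and indirect interactions are removed
#' using the data-processing inequality. For each triplet
#' \eqn{(i, j, k)} with all three similarities positive, edge
#' \eqn{(i, j)} is marked for removal iff
#' \eqn{w_{ij} < \min(w_{ik}, w_{jk}) - \epsilon}. All marks are
#' evaluated against the original matrix and the removals applied
#' simultaneously in a single pass, so the operation is deterministic
#' and re-applying it with the same input matrix changes nothing.
#' Surviving edges keep their original weight.
#'
#' @param x a \code{\linkS4class{MIMatrix}} or a symmetric non-negative
#'   numeric matrix with zero diagonal.
#' @param epsilon DPI tolerance \eqn{\epsilon \ge 0}; larger values make
#'   removal harder. Default 0, the canonical DPI.
#' @return a \code{\linkS4class{GeneNetwork}} whose edge set is a subset
#'   of the positive entries of \code{x}.
#' @examples
#' m <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
#' m["a", "b"] <- m["b", "a"] <- 0.5
#' m["b", "c"] <- m["c", "b"] <- 0.4
#' m["a", "c"] <- m["c", "a"] <- 0.1
#' adjacency(aracne(m))  # a-c removed: 0.1 < min(0.5, 0.4)
#' @export
aracne <- function(x, epsilon = 0) {
    prov <- "cmi"
    if (is(x, "MIMatrix")) {
        prov <- if (x@estimator == "spearman_gaussian") "spearman" else "cmi"
        M <- x@mim
    } else {
        M <- x
    }
    chk <- .checkSquareSym(M, "similarity matrix")
    if (!isTRUE(chk))
        stop(chk[1])
    if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0)
        stop("epsilon must be a single number >= 0")
    p <- nrow(M)
    A <- M
    if (p > 2) {
        # For row i, cand[j, k] = min(M[i, k], M[j, k]); since M >= 0 with a
        # zero diagonal, triplets with any zero similarity can never satisfy
        # the strict removal inequality, so no masking is needed.
        for (i in seq_len(p)) {
            cand <- pmin(matrix(M[i, ], p, p, byrow = TRUE), M)
            thr <- cand[cbind(seq_len(p), max.col(cand, ties.method = "first"))]
            drop <- M[i, ] > 0 & (M[i, ] < thr - epsilon)
            A[i, drop] <- 0
        }
        A[t(A) == 0] <- 0  # marks are symmetric; enforce exactly
    }
    new("GeneNetwork", adjacency = A, provenance = prov,
        dpiEpsilon = as.numeric(epsilon))
}
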