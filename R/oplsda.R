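# autoscale columns; zero-variance columns become all-zero
.autoscale <- function(X) {
    mu <- colMeans(X)
    sdv <- apply(X, 2, stats::sd)
    sdv[sdv == 0] <- Inf
    sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")
}

.oneHot <- function(y) {
    y <- as.factor(y)
    Y <- stats::model.matrix(~ y - 1)
    colnames(Y) <- levels(y)
    Y
}

# NIPALS PLS2: returns scores T, loadings P, Y-loadings Q, weights W
.plsNipals <- function(X, Y, ncomp, tol = 1e-10, maxIter = 500) {
    Tm <- matrix(0, nrow(X), ncomp)
    P <- matrix(0, ncol(X), ncomp)
    W <- matrix(0, ncol(X), ncomp)
    Xd <- X
    Yd <- Y
    for (a in seq_len(ncomp)) {
        u <- Yd[, which.max(colSums(Yd^2))]
        tOld <- rep(Inf, nrow(X))
        for (it in seq_len(maxIter)) {
            w <- crossprod(Xd, u)
            w <- w / sqrt(sum(w^2))
            tt <- Xd %*% w
            q <- crossprod(Yd, tt) / sum(tt^2)
            u <- Yd %*% q / sum(q^2)
            if (sum((tt - tOld)^2) < tol * sum(tt^2))
                break
            tOld <- tt
        }
        p <- crossprod(Xd, tt) / sum(tt^2)
        Xd <- Xd - tt %*% t(p)
        qy <- crossprod(Yd, tt) / sum(tt^2)
        Yd <- Yd - tt %*% t(qy)
        Tm[, a] <- tt
        P[, a] <- p
        W[, a] <- w
    }
    list(scores = Tm, loadings = P, weights = W, Xres = Xd)
}

# one orthogonal-signal-correction component (O-PLS, multi-class Y):
# the part of the first PLS loading orthogonal to the Y-predictive
# weight space is removed from X
.oscComponent <- function(X, Y) {
    Wy <- crossprod(X, Y)                       # p x classes
    qq <- qr(Wy)                                # rank-revealing basis:
    Wy <- qr.Q(qq)[, seq_len(qq$rank), drop = FALSE]  # centered one-hot
    # Y has rank (classes - 1), so surplus QR columns must be dropped
    fit <- .plsNipals(X, Y, 1L)
    p <- fit$loadings[, 1]
    wOrtho <- p - Wy %*% crossprod(Wy, p)
    nrmW <- sqrt(sum(wOrtho^2))
    if (nrmW < 1e-12)
        return(list(X = X, removed = FALSE))
    wOrtho <- wOrtho / nrmW
    tOrtho <- X %*% wOrtho
    pOrtho <- crossprod(X, tOrtho) / sum(tOrtho^2)
    list(X = X - tOrtho %*% t(pOrtho), removed = TRUE)
}

#' Fit an O-PLS-DA model
#'
#' Orthogonal-signal-correction partial least squares discriminant
#' analysis: class labels are one-hot encoded, predictors are
#' mean-centered and unit-variance scaled, \code{nOrtho} components of
#' X-variation orthogonal to the class space are removed, and a NIPALS
#' PLS2 model with \code{nPredictive} components is fit on the filtered
#' matrix. \code{Xvar} is the percent of total (scaled) predictor
#' variance captured by the predictive components. With
#' \code{nOrtho = 0} the fit reduces exactly to plain PLS-DA.
#'
#' @param X samples-by-genes numeric matrix.
#' @param y class labels (factor or coercible), >= 2 classes with >= 2
#'   samples each.
#' @param nPredictive number of predictive components (default 2).
#' @param nOrtho number of orthogonal components to remove (default 1);
#'   must be below the rank of the scaled X.
#' @param seed integer seed (recorded; the fit itself is
#'   deterministic).
#' @return an \code{\linkS4class{OplsdaResult}}.
#' @export
fitOplsda <- function(X, y, nPredictive = 2, nOrtho = 1, seed = 1) {
    X <- as.matrix(X)
    y <- as.factor(y)
    y <- droplevels(y)
    if (nlevels(y) < 2)
        stop("need at least two classes")
    if (any(table(y) < 2))
        stop("every class needs at least two samples")
    if (length(y) != nrow(X))
        stop("length(y) must equal nrow(X)")
    Xs <- .autoscale(X)
    rk <- qr(Xs)$rank
    if (nOrtho >= rk)
        stop(sprintf("nOrtho (%d) must be below rank(X) (%d)", nOrtho, rk))
    Y <- scale(.oneHot(y), center = TRUE, scale = FALSE)
    Xf <- Xs
    removed <- 0L
    while (removed < nOrtho) {
        osc <- .oscComponent(Xf, Y)
        if (!osc$removed)
            break
        Xf <- osc$X
        removed <- removed + 1L
    }
    ncomp <- min(nPredictive, rk - removed, nlevels(y))
    fit <- .plsNipals(Xf, Y, ncomp)
    ssTot <- sum(Xs^2)
    ssPred <- sum((fit$scores %*% t(fit$loadings))^2)
    xvar <- 100 * ssPred / ssTot
    rownames(fit$scores) <- rownames(X)
    colnames(fit$scores) <- sprintf("p%d", seq_len(ncomp))
    new("OplsdaResult", scores = fit$scores, nOrtho = removed,
        xvar = xvar, permP = NA_real_, nPermutations = 0L,
        seed = as.integer(seed))
}

#' Permutation validation of an O-PLS-DA model
#'
#' Refits the full model (orthogonal filtering included) under seeded
#' label permutations and reports
#' \eqn{p = (1 + \#\{Xvar_{perm} \ge Xvar_{obs}\}) / (n_{perm} + 1)},
#' whose smallest attainable value is \eqn{1/(n_{perm}+1)}.
#'
#' @inheritParams fitOplsda
#' @param nPermutations number of label permutations (>= 99; default
#'   999).
#' @return an \code{\linkS4class{OplsdaResult}} for the observed labels
#'   with \code{permP} and \code{nPermutations} filled in; the
#'   permutation Xvar distribution is attached as attribute
#'   \code{"permXvar"}.
#' @export
oplsdaPermutationTest <- function(X, y, nPermutations = 999, seed = 1,
    nPredictive = 2, nOrtho = 1) {
    if (nPermutations < 99)
        stop("nPermutations must be >= 99")
    obs <- fitOplsda(X, y, nPredictive, nOrtho, seed)
    permXvar <- .withSeed(seed, vapply(seq_len(nPermutations), function(b) {
        yp <- sample(y)
        fitOplsda(X, yp, nPredictive, nOrtho, seed)@xvar
    }, numeric(1)))
    p <- (1 + sum(permXvar >= obs@xvar)) / (nPermutations + 1)
    res <- new("OplsdaResult", scores = obs@scores, nOrtho = obs@nOrtho,
        xvar = obs@xvar, permP = p,
        nPermutations = as.integer(nPermutations),
        seed = as.integer(seed))
    attr(res, "permXvar") <- permXvar
    res
}
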