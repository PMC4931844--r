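#' Specify a synthetic graded-treatment expression study
#'
#' Builds a validated \code{\linkS4class{SyntheticSpec}}. The defaults
#' emulate the hypothalamic graded calorie-restriction design this
#' package targets: 408 genes, six ordered treatment levels (12h ad
#' libitum reference, 24h ad libitum, then 10-40\% restriction) with
#' 6, 6, 7, 5, 5 and 8 samples, modular structure that rewires
#' increasingly with restriction level, one hub gene per cluster, and a
#' fraction of U-shaped (non-monotone) gene-factor links.
#'
#' @param nGenes number of genes (default 408).
#' @param nClusters number of planted clusters (default 10); ignored if
#'   \code{clusterSizes} is given.
#' @param clusterSizes integer vector of cluster sizes summing to
#'   \code{nGenes}; defaults to a near-equal split.
#' @param treatmentLevels ordered treatment labels.
#' @param samplesPerLevel samples per level, same length.
#' @param rewireFraction per-level fraction of genes reassigned to a
#'   different cluster, relative to the first level.
#' @param hubGenes gene indices acting as hubs; defaults to the first
#'   gene of every cluster. Use \code{integer(0)} for none.
#' @param hubMultiplier hub loading multiplier (default 3); a vector of
#'   one value per treatment level makes hub strength change along the
#'   gradient.
#' @param crossLoading hub loading on ring-neighbour cluster factors
#'   (default 0.15, kept below the noise floor so cross-cluster wiring
#'   does not drown the hub's own-factor alignment).
#' @param factorCor exchangeable correlation between cluster factors
#'   (default 0.3): co-expression modules in one tissue share a global
#'   regulatory state, so between-cluster dependence is weak but not
#'   zero.
#' @param nonmonotoneFraction fraction of each cluster's (non-hub)
#'   genes given a quadratic link to the factor (default 0.2).
#' @param factorTrend magnitude of the graded per-cluster factor mean
#'   shift along the gradient (default 1.5): each cluster's latent
#'   factor drifts up or down with restriction level, emulating the
#'   coordinated physiological state shift that lets expression
#'   predict treatment; within-level dependence is unaffected.
#' @param deFraction fraction of genes differentially expressed along
#'   the gradient (default 0.1, roughly matching the handfuls of
#'   treatment-responsive genes such designs report).
#' @param deMagnitude maximum absolute log-scale mean shift, reached at
#'   the last level and scaled linearly with level index (default 1).
#' @param noiseSd additive log-scale noise SD (default 0.3).
#' @param seed integer seed.
#' @return a \code{\linkS4class{SyntheticSpec}}.
#' @export
syntheticSpec <- function(nGenes = 408, nClusters = 10, clusterSizes = NULL,
    treatmentLevels = c("12AL", "24AL", "10CR", "20CR", "30CR", "40CR"),
    samplesPerLevel = c(6, 6, 7, 5, 5, 8),
    rewireFraction = c(0, 0.05, 0.10, 0.15, 0.20, 0.30),
    hubGenes = NULL, hubMultiplier = 3, crossLoading = 0.15,
    factorCor = 0.3, nonmonotoneFraction = 0.2, factorTrend = 1.5,
    deFraction = 0.1, deMagnitude = 1, noiseSd = 0.3, seed = 1) {
    if (is.null(clusterSizes)) {
        clusterSizes <- rep(nGenes %/% nClusters, nClusters)
        rem <- nGenes - sum(clusterSizes)
        if (rem > 0)
            clusterSizes[seq_len(rem)] <- clusterSizes[seq_len(rem)] + 1L
    }
    if (is.null(hubGenes))
        hubGenes <- cumsum(c(1L, utils::head(clusterSizes, -1)))
    new("SyntheticSpec", nGenes = as.integer(nGenes),
        clusterSizes = as.integer(clusterSizes),
        treatmentLevels = as.character(treatmentLevels),
        samplesPerLevel = as.integer(samplesPerLevel),
        rewireFraction = as.numeric(rewireFraction),
        hubGenes = as.integer(hubGenes),
        hubMultiplier = as.numeric(hubMultiplier),
        crossLoading = as.numeric(crossLoading),
        factorCor = as.numeric(factorCor),
        nonmonotoneFraction = as.numeric(nonmonotoneFraction),
        factorTrend = as.numeric(factorTrend),
        deFraction = as.numeric(deFraction),
        deMagnitude = as.numeric(deMagnitude),
        noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
}

#' Generate a synthetic expression study with planted structure
#'
#' Latent-factor generative model: each cluster is driven by one
#' standard-normal factor per treatment level; the factors share an
#' exchangeable correlation \code{factorCor} through a global factor. A
#' gene's log-expression is \code{loading * factor + noise} (monotone
#' link) or \code{loading * (factor^2 - 1)/sqrt(2) + noise} (planted
#' U-shaped link, Spearman-null against linear cluster-mates but
#' mutual-information positive). Hub genes load on their own factor
#' with \code{hubMultiplier} and weakly on ring-neighbour cluster
#' factors, which makes them the highest-centrality nodes of the
#' inferred networks. Per level, a seeded subset of genes is reassigned
#' to a different cluster (graded rewiring relative to the first
#' level), and a seeded subset of genes carries a signed log-scale mean
#' shift that grows linearly along the gradient (graded differential
#' expression, which is what the classification stage detects). Values
#' are exponentiated onto a positive normalized-count-like scale.
#' Output is byte-identical for identical spec and seed.
#'
#' @param spec a \code{\linkS4class{SyntheticSpec}}.
#' @return a \code{SummarizedExperiment} (assay \code{"expr"}, genes by
#'   samples; \code{colData$treatment} ordered factor) whose
#'   \code{metadata} holds \code{spec} and \code{truth}: base and
#'   per-level cluster \code{assignments} (genes by levels), \code{hubs}
#'   (gene ids), \code{quadGenes}, \code{nonmonotonePairs} (planted
#'   U-shaped within-cluster pairs), \code{deGenes} and \code{deShift}
#'   (per-gene maximum log-scale shift).
#' @export
generateExpression <- function(spec) {
    stopifnot(is(spec, "SyntheticSpec"))
    validObject(spec)
    set.seed(spec@seed)
    k <- length(spec@clusterSizes)
    p <- spec@nGenes
    L <- length(spec@treatmentLevels)
    geneIds <- sprintf("g%04d", seq_len(p))
    base <- rep(seq_len(k), spec@clusterSizes)

    loading <- stats::runif(p, 0.6, 1)
    isHub <- seq_len(p) %in% spec@hubGenes
    hm <- rep(spec@hubMultiplier, length.out = L)

    quad <- logical(p)
    for (cl in seq_len(k)) {
        members <- which(base == cl & !isHub)
        nq <- round(spec@nonmonotoneFraction * length(members))
        if (nq > 0)
            quad[sample(members, nq)] <- TRUE
    }

    assign <- matrix(base, p, L,
        dimnames = list(geneIds, spec@treatmentLevels))
    for (l in seq_len(L)) {
        nrw <- round(spec@rewireFraction[l] * p)
        if (nrw > 0) {
            moved <- sample(p, nrw)
            shift <- sample(k - 1, nrw, replace = TRUE)
            assign[moved, l] <- ((base[moved] - 1L + shift) %% k) + 1L
        }
    }

    # graded state shift: per-cluster signed factor-mean drift along the
    # gradient (only meaningful with more than one level)
    trendShift <- numeric(k)
    if (L > 1 && spec@factorTrend > 0)
        trendShift <- sample(c(-1, 1), k, replace = TRUE) *
            stats::runif(k, 0.5, 1) * spec@factorTrend

    nTot <- sum(spec@samplesPerLevel)
    X <- matrix(0, p, nTot)
    sampleIds <- character(nTot)
    treatment <- character(nTot)
    col0 <- 0L
    for (l in seq_len(L)) {
        nl <- spec@samplesPerLevel[l]
        g0 <- stats::rnorm(nl)
        FF <- sqrt(spec@factorCor) * matrix(g0, nl, k) +
            sqrt(1 - spec@factorCor) * matrix(stats::rnorm(nl * k), nl, k)
        if (L > 1)
            FF <- FF + matrix(trendShift * (l - 1) / (L - 1), nl, k,
                byrow = TRUE)
        al <- assign[, l]
        fOwn <- FF[, al, drop = FALSE]                      # nl x p
        sig <- t(fOwn) * loading                            # p x nl
        if (any(quad))
            sig[quad, ] <- loading[quad] *
                (t(fOwn[, quad, drop = FALSE])^2 - 1) / sqrt(2)
        if (any(isHub)) {
            for (h in which(isHub)) {
                own <- al[h]
                nb <- unique(c(((own - 2) %% k) + 1, (own %% k) + 1))
                nb <- setdiff(nb, own)
                cross <- if (length(nb))
                    spec@crossLoading * rowSums(FF[, nb, drop = FALSE])
                else 0
                sig[h, ] <- hm[l] * loading[h] * FF[, own] + cross
            }
        }
        z <- sig + matrix(stats::rnorm(p * nl, sd = spec@noiseSd), p, nl)
        cols <- col0 + seq_len(nl)
        X[, cols] <- exp(z)
        sampleIds[cols] <- sprintf("%s_%d", spec@treatmentLevels[l],
            seq_len(nl))
        treatment[cols] <- spec@treatmentLevels[l]
        col0 <- col0 + nl
    }
    dimnames(X) <- list(geneIds, sampleIds)

    # graded differential expression: a seeded gene subset gets a signed
    # log-scale mean shift growing linearly along the level gradient
    nDe <- round(spec@deFraction * p)
    deGenes <- if (nDe > 0) sort(sample(p, nDe)) else integer(0)
    deShift <- numeric(p)
    if (nDe > 0 && L > 1) {
        deShift[deGenes] <- sample(c(-1, 1), nDe, replace = TRUE) *
            stats::runif(nDe, 0.5, 1) * spec@deMagnitude
        for (l in seq_len(L)) {
            cols <- treatment == spec@treatmentLevels[l]
            X[deGenes, cols] <- X[deGenes, cols] *
                exp(deShift[deGenes] * (l - 1) / (L - 1))
        }
    }

    quadIds <- geneIds[quad]
    pairs <- do.call(rbind, lapply(which(quad), function(q) {
        lin <- which(base == base[q] & !quad)
        if (!length(lin)) return(NULL)
        data.frame(gene1 = geneIds[q], gene2 = geneIds[lin],
            cluster = base[q], stringsAsFactors = FALSE)
    }))
    if (is.null(pairs))
        pairs <- data.frame(gene1 = character(0), gene2 = character(0),
            cluster = integer(0))

    truth <- list(base = stats::setNames(base, geneIds),
        assignments = assign, hubs = geneIds[isHub],
        quadGenes = quadIds, nonmonotonePairs = pairs,
        deGenes = geneIds[deGenes],
        deShift = stats::setNames(deShift, geneIds),
        factorTrend = trendShift)
    SummarizedExperiment::SummarizedExperiment(
        assays = list(expr = X),
        colData = S4Vectors::DataFrame(
            treatment = factor(treatment, levels = spec@treatmentLevels),
            row.names = sampleIds),
        metadata = list(spec = spec, truth = truth))
}
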