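#' Pipeline configuration
#'
#' Assembles and validates the single configuration object driving
#' \code{\link{runPipeline}}: every tunable of the analysis lives here,
#' so one configuration plus one seed yields one reproducible report.
#'
#' @param exprFile,metadataFile input TSV paths (ignored when the
#'   expression object is passed to \code{runPipeline} directly).
#' @param treatmentLevels ordered treatment labels to analyze.
#' @param referenceLevel reference level (must be among
#'   \code{treatmentLevels}).
#' @param estimators similarity estimators to run: subset of
#'   \code{c("cmi", "spearman")}.
#' @param bins bins per gene for the MI estimator; \code{NULL} = the
#'   square-root default.
#' @param scheme discretization scheme.
#' @param epsilon DPI tolerance for ARACNE.
#' @param tau central-gene centrality threshold.
#' @param seed integer seed for community detection.
#' @param outDir optional output directory for per-network artifacts.
#' @return a named list of class \code{crnetConfig}.
#' @export
pipelineConfig <- function(exprFile = NULL, metadataFile = NULL,
    treatmentLevels = c("12AL", "24AL", "10CR", "20CR", "30CR", "40CR"),
    referenceLevel = "12AL", estimators = c("cmi", "spearman"),
    bins = NULL, scheme = "equal_frequency", epsilon = 0, tau = 0.9,
    seed = 1, outDir = NULL) {
    estimators <- match.arg(estimators, several.ok = TRUE)
    if (!referenceLevel %in% treatmentLevels)
        stop(sprintf("reference level '%s' is not among the treatment levels",
            referenceLevel))
    cfg <- list(exprFile = exprFile, metadataFile = metadataFile,
        treatmentLevels = as.character(treatmentLevels),
        referenceLevel = referenceLevel, estimators = estimators,
        bins = bins, scheme = scheme, epsilon = epsilon, tau = tau,
        seed = as.integer(seed), outDir = outDir)
    class(cfg) <- c("crnetConfig", "list")
    cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param file YAML file whose keys match the arguments of
#'   \code{\link{pipelineConfig}}.
#' @return a \code{crnetConfig} list.
#' @export
readPipelineConfig <- function(file) {
    y <- yaml::read_yaml(file)
    do.call(pipelineConfig, y[intersect(names(y),
        names(formals(pipelineConfig)))])
}

#' Per-gene centrality trend across ordered levels
#'
#' Spearman correlation of each gene's centrality trajectory against
#' the ordinal level index. The sign classifies the gene as
#' \code{"graded-up"} (\eqn{\rho > 0}), \code{"graded-down"}
#' (\eqn{\rho < 0}) or \code{"flat"} (zero or undefined, e.g. a
#' constant trajectory). Missing levels are dropped per gene; genes
#' observed at fewer than three levels are excluded (\code{NA} trend).
#'
#' @param trajectories genes-by-levels numeric matrix (NA = gene not
#'   measurable at that level).
#' @param levelOrder optional level labels defining the order
#'   (defaults to column order).
#' @return data.frame with \code{gene}, \code{rho}, \code{nLevels},
#'   \code{trend}.
#' @export
centralityTrend <- function(trajectories, levelOrder = NULL) {
    if (!is.null(levelOrder))
        trajectories <- trajectories[, levelOrder, drop = FALSE]
    if (ncol(trajectories) < 3)
        stop("need at least three levels")
    idx <- seq_len(ncol(trajectories))
    res <- lapply(seq_len(nrow(trajectories)), function(g) {
        v <- trajectories[g, ]
        ok <- !is.na(v)
        if (sum(ok) < 3)
            return(c(rho = NA_real_, n = sum(ok)))
        if (stats::sd(v[ok]) == 0)
            return(c(rho = 0, n = sum(ok)))
        c(rho = suppressWarnings(stats::cor(v[ok], idx[ok],
            method = "spearman")), n = sum(ok))
    })
    rho <- vapply(res, `[[`, numeric(1), "rho")
    nlev <- vapply(res, `[[`, numeric(1), "n")
    trend <- ifelse(is.na(rho), NA_character_,
        ifelse(rho > 0, "graded-up", ifelse(rho < 0, "graded-down", "flat")))
    trend[!is.na(rho) & rho == 0] <- "flat"
    data.frame(gene = rownames(trajectories), rho = rho, nLevels = nlev,
        trend = trend, stringsAsFactors = FALSE)
}

# canonical JSON of a report (numbers at full precision, fixed ordering)
.reportJson <- function(rep) {
    jsonlite::toJSON(list(
        summary = rep@summaryTable,
        centrality = lapply(rep@centrality, function(m)
            as.data.frame(round(m, 12))),
        trends = rep@trends,
        flows = lapply(rep@flows, function(fl) lapply(fl, function(f)
            list(from = f$from, to = f$to, ari = f$ari,
                table = as.data.frame(f$table)))),
        centralOverlap = rep@centralOverlap,
        config = rep@config[setdiff(names(rep@config), "outDir")]),
        digits = NA, auto_unbox = TRUE, na = "null")
}

#' Run the full per-treatment network comparison pipeline
#'
#' For every treatment level and estimator: subset the samples, build
#' the similarity matrix (Miller-Madow MI or the Spearman proxy), prune
#' it with ARACNE, detect modularity-based communities, compute
#' eigenvector centrality and central genes; then assemble the
#' cross-treatment comparison: a summary table of modularity and
#' cluster counts per network, per-gene centrality trajectories with
#' trend statistics, consecutive-level cluster flows, and the
#' CMI-versus-correlation central-gene overlap. Treatments with fewer
#' than three samples are skipped with a warning; a declared treatment
#' missing from the data is an error before any computation. The
#' report carries an md5 hash of its canonical JSON serialization, so
#' identical configuration and seed give hash-identical reports.
#'
#' @param x a \code{SummarizedExperiment} (or \code{NULL} to read from
#'   the files named in \code{config}).
#' @param config a \code{crnetConfig} from \code{\link{pipelineConfig}}.
#' @return a \code{\linkS4class{ComparisonReport}}; per-network
#'   artifacts are written under \code{config$outDir} if set.
#' @export
runPipeline <- function(x = NULL, config = pipelineConfig()) {
    if (is.null(x)) {
        if (is.null(config$exprFile) || is.null(config$metadataFile))
            stop("config must name exprFile and metadataFile when no expression object is given")
        x <- readExpression(config$exprFile, config$metadataFile,
            config$treatmentLevels)
    }
    tr <- as.character(SummarizedExperiment::colData(x)$treatment)
    missing <- setdiff(config$treatmentLevels, unique(tr))
    if (length(missing))
        stop(sprintf("treatment level(s) not present in the data: %s",
            paste(missing, collapse = ", ")))
    counts <- table(tr)[config$treatmentLevels]
    levels <- config$treatmentLevels
    skip <- levels[counts[levels] < 3]
    if (length(skip)) {
        warning(sprintf("skipping treatment(s) with < 3 samples: %s",
            paste(skip, collapse = ", ")))
        levels <- setdiff(levels, skip)
    }
    genes <- rownames(x)
    outDir <- config$outDir
    if (!is.null(outDir) && !dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)

    rows <- list()
    centr <- list()
    parts <- list()
    central <- list()
    for (est in config$estimators) {
        cm <- matrix(NA_real_, length(genes), length(levels),
            dimnames = list(genes, levels))
        parts[[est]] <- list()
        central[[est]] <- list()
        for (lev in levels) {
            sim <- if (est == "cmi")
                buildMIM(x, treatment = lev, bins = config$bins,
                    scheme = config$scheme)
            else spearmanSimilarity(x, treatment = lev)
            net <- aracne(sim, epsilon = config$epsilon)
            part <- detectCommunities(net, seed = config$seed)
            prof <- suppressWarnings(eigenvectorCentrality(net))
            cg <- identifyCentralGenes(prof, tau = config$tau)
            ns <- networkSummary(net)
            cm[, lev] <- centralities(prof)
            cm[setdiff(seq_along(genes), prof@component), lev] <- NA
            parts[[est]][[lev]] <- part
            central[[est]][[lev]] <- cg
            rows[[length(rows) + 1]] <- data.frame(treatment = lev,
                estimator = est, modularity = modularityQ(part),
                clusters = nClusters(part), edges = ns$edges,
                meanDegree = ns$meanDegree, components = ns$components,
                centralGenes = paste(cg, collapse = ","),
                stringsAsFactors = FALSE)
            if (!is.null(outDir)) {
                base <- file.path(outDir, sprintf("%s_%s", lev, est))
                writeNetwork(net, paste0(base, "_edges.tsv"),
                    paste0(base, ".graphml"))
                utils::write.table(data.frame(gene_id = genes,
                    cluster = clusterAssignments(part)[genes]),
                    paste0(base, "_clusters.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
            }
        }
        centr[[est]] <- cm
    }
    summaryTable <- do.call(rbind, rows)
    trends <- lapply(centr, function(m)
        if (ncol(m) >= 3) centralityTrend(m) else NULL)
    trends <- trends[!vapply(trends, is.null, logical(1))]
    flows <- lapply(parts, function(pl) clusterCrosstab(pl,
        labels = names(pl)))
    overlap <- if (all(c("cmi", "spearman") %in% config$estimators)) {
        do.call(rbind, lapply(levels, function(lev) {
            a <- central$cmi[[lev]]
            b <- central$spearman[[lev]]
            data.frame(treatment = lev, nCmi = length(a),
                nSpearman = length(b),
                overlap = length(intersect(a, b)),
                shared = paste(intersect(a, b), collapse = ","),
                stringsAsFactors = FALSE)
        }))
    } else {
        data.frame()
    }
    rep <- new("ComparisonReport", summaryTable = summaryTable,
        centrality = centr, trends = trends, flows = flows,
        centralOverlap = overlap,
        config = config[setdiff(names(config), "outDir")],
        hash = "")
    rep@hash <- reportHash(rep)
    if (!is.null(outDir)) {
        writeLines(as.character(.reportJson(rep)),
            file.path(outDir, "report.json"))
        utils::write.table(summaryTable[, c("treatment", "estimator",
            "modularity", "clusters")],
            file.path(outDir, "modularity_table.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
    }
    rep
}

#' md5 hash of a comparison report
#'
#' Hash of the canonical JSON serialization (configuration included,
#' output paths excluded); two runs with identical configuration and
#' seed produce identical hashes.
#'
#' @param rep a \code{\linkS4class{ComparisonReport}}.
#' @return character md5 digest.
#' @export
reportHash <- function(rep) {
    stopifnot(is(rep, "ComparisonReport"))
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp))
    writeLines(as.character(.reportJson(rep)), tmp)
    unname(tools::md5sum(tmp))
}
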