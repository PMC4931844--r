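#' Read an expression study from TSV files
#'
#' Expression file: genes x samples TSV, first column gene ids, header
#' = sample ids. Metadata file: TSV with columns \code{sample_id} and
#' \code{treatment}.
#'
#' @param exprFile path to the expression TSV.
#' @param metadataFile path to the sample-metadata TSV.
#' @param treatmentLevels optional ordered level labels (defaults to
#'   order of first appearance).
#' @return a \code{SummarizedExperiment} with assay \code{"expr"} and
#'   \code{colData$treatment}.
#' @export
readExpression <- function(exprFile, metadataFile, treatmentLevels = NULL) {
    ex <- utils::read.delim(exprFile, check.names = FALSE,
        stringsAsFactors = FALSE)
    genes <- as.character(ex[[1]])
    if (anyDuplicated(genes))
        stop("gene ids must be unique")
    m <- as.matrix(ex[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- genes
    if (anyNA(m))
        stop("expression matrix must not contain missing values")
    md <- utils::read.delim(metadataFile, stringsAsFactors = FALSE)
    if (!all(c("sample_id", "treatment") %in% colnames(md)))
        stop("metadata needs columns 'sample_id' and 'treatment'")
    if (!setequal(md$sample_id, colnames(m)))
        stop("metadata sample ids do not match expression columns")
    md <- md[match(colnames(m), md$sample_id), ]
    if (is.null(treatmentLevels))
        treatmentLevels <- unique(md$treatment)
    SummarizedExperiment::SummarizedExperiment(
        assays = list(expr = m),
        colData = S4Vectors::DataFrame(
            treatment = factor(md$treatment, levels = treatmentLevels),
            row.names = md$sample_id))
}

#' Write an expression study as TSV files
#'
#' Writes \code{expression.tsv} (genes x samples), \code{samples.tsv}
#' (sample_id, treatment) and, when the study carries planted truth,
#' \code{truth.json}.
#'
#' @param se a \code{SummarizedExperiment} as produced by
#'   \code{\link{generateExpression}} or \code{\link{readExpression}}.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
writeExpression <- function(se, dir) {
    if (!dir.exists(dir))
        dir.create(dir, recursive = TRUE)
    m <- SummarizedExperiment::assay(se)
    exprPath <- file.path(dir, "expression.tsv")
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, exprPath, sep = "\t", quote = FALSE,
        row.names = FALSE)
    mdPath <- file.path(dir, "samples.tsv")
    utils::write.table(data.frame(sample_id = colnames(m),
        treatment = as.character(SummarizedExperiment::colData(se)$treatment)),
        mdPath, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(exprPath, mdPath)
    truth <- S4Vectors::metadata(se)$truth
    if (!is.null(truth)) {
        truthPath <- file.path(dir, "truth.json")
        jsonlite::write_json(list(base = as.list(truth$base),
            assignments = as.data.frame(truth$assignments),
            hubs = truth$hubs, quadGenes = truth$quadGenes,
            nonmonotonePairs = truth$nonmonotonePairs,
            deGenes = truth$deGenes,
            deShift = as.list(truth$deShift)),
            truthPath, auto_unbox = TRUE, digits = NA)
        paths <- c(paths, truthPath)
    }
    invisible(paths)
}

#' Write a network as edge-list TSV and GraphML
#'
#' @param net a \code{\linkS4class{GeneNetwork}}.
#' @param edgeListFile path for a weighted edge-list TSV
#'   (\code{gene_a}, \code{gene_b}, \code{weight}), or \code{NULL}.
#' @param graphmlFile path for a GraphML file, or \code{NULL}.
#' @return invisibly, the paths written.
#' @export
writeNetwork <- function(net, edgeListFile = NULL, graphmlFile = NULL) {
    stopifnot(is(net, "GeneNetwork"))
    paths <- character(0)
    if (!is.null(edgeListFile)) {
        a <- net@adjacency
        idx <- which(upper.tri(a) & a > 0, arr.ind = TRUE)
        el <- data.frame(gene_a = rownames(a)[idx[, 1]],
            gene_b = colnames(a)[idx[, 2]], weight = a[idx])
        el <- el[order(el$gene_a, el$gene_b), ]
        utils::write.table(el, edgeListFile, sep = "\t", quote = FALSE,
            row.names = FALSE)
        paths <- c(paths, edgeListFile)
    }
    if (!is.null(graphmlFile)) {
        igraph::write_graph(.asIgraph(net), graphmlFile, format = "graphml")
        paths <- c(paths, graphmlFile)
    }
    invisible(paths)
}

#' Read a network from an edge-list TSV
#'
#' @param edgeListFile TSV with columns \code{gene_a}, \code{gene_b},
#'   \code{weight}.
#' @param genes optional full gene universe (isolated genes included).
#' @param provenance tag for the resulting network.
#' @return a \code{\linkS4class{GeneNetwork}}.
#' @export
readNetwork <- function(edgeListFile, genes = NULL, provenance = "cmi") {
    el <- utils::read.delim(edgeListFile, stringsAsFactors = FALSE)
    if (is.null(genes))
        genes <- sort(unique(c(el$gene_a, el$gene_b)))
    a <- matrix(0, length(genes), length(genes),
        dimnames = list(genes, genes))
    a[cbind(el$gene_a, el$gene_b)] <- el$weight
    a[cbind(el$gene_b, el$gene_a)] <- el$weight
    geneNetwork(a, provenance = provenance)
}

#' Write a similarity matrix as TSV
#'
#' @param x a \code{\linkS4class{MIMatrix}}.
#' @param file output path; gene ids as row and column labels.
#' @return invisibly, the path.
#' @export
writeMIM <- function(x, file) {
    stopifnot(is(x, "MIMatrix"))
    df <- data.frame(gene_id = rownames(x@mim), x@mim, check.names = FALSE)
    utils::write.table(df, file, sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(file)
}

#' Read a similarity matrix from TSV
#'
#' @param file TSV written by \code{\link{writeMIM}}.
#' @param estimator estimator tag of the matrix.
#' @return a \code{\linkS4class{MIMatrix}}.
#' @export
readMIM <- function(file, estimator = "miller_madow") {
    df <- utils::read.delim(file, check.names = FALSE,
        stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- df[[1]]
    m <- (m + t(m)) / 2
    diag(m) <- 0
    new("MIMatrix", mim = m, estimator = estimator)
}
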