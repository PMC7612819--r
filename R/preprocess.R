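#' Filter low-quality cells by library size and detected genes
#'
#' Retains cells with total raw counts >= \code{minReads} and detected genes
#' >= \code{minGenes}, in their original order. Defaults match the atlas QC
#' thresholds (2000 reads, 500 genes).
#'
#' @param cells a \code{SingleCellExperiment} with a \code{"counts"} assay
#'   (genes x cells).
#' @param minReads minimum total counts per cell.
#' @param minGenes minimum number of genes with nonzero counts per cell.
#' @return the filtered \code{SingleCellExperiment}.
#' @export
#' @importFrom SummarizedExperiment assay assays colData rowData
qcFilter <- function(cells, minReads = 2000, minGenes = 500) {
    stopifnot(minReads >= 0, minGenes >= 0)
    m <- assay(cells, "counts")
    keep <- Matrix::colSums(m) >= minReads &
        Matrix::colSums(m > 0) >= minGenes
    if (!any(keep)) warning("no cells pass QC thresholds")
    cells[, keep]
}

#' Depth-normalize counts and log-transform
#'
#' Scales each cell's counts to a common total, then applies ln(x + 1).
#' Raw counts stay untouched in the \code{"counts"} assay; the result is
#' stored as (and returned from) the \code{"lognorm"} assay.
#'
#' @param cells a \code{SingleCellExperiment} with \code{"counts"}.
#' @param targetSum per-cell total after scaling (default 1e4).
#' @return \code{cells} with an added dense \code{"lognorm"} assay.
#' @export
normalizeLog <- function(cells, targetSum = 1e4) {
    m <- assay(cells, "counts")
    tot <- Matrix::colSums(m)
    if (any(tot == 0))
        stop("all-zero cell(s): ",
             paste(head(colnames(m)[tot == 0], 5), collapse = ", "),
             " - run qcFilter first")
    sf <- targetSum / tot
    norm <- m %*% Matrix::Diagonal(x = sf)
    dimnames(norm) <- dimnames(m)
    SummarizedExperiment::assay(cells, "lognorm") <- log1p(norm)
    cells
}

#' Select highly variable genes by binned normalized dispersion
#'
#' Genes are ranked by dispersion (variance/mean of the depth-normalized
#' values, back-transformed from the log assay to the linear scale, which is
#' the scale the stated mean window refers to), z-scored within 20
#' equal-frequency mean bins so that the ranking is not mean-driven,
#' restricted to the stated mean window, and the top \code{nTop} returned
#' after removing any exclusion lists (e.g. cell-cycle and TCR/BCR genes).
#' Defaults follow the atlas settings (min_mean = 0.001, max_mean = 10,
#' 7500 genes).
#'
#' @param cells a \code{SingleCellExperiment} with a \code{"lognorm"} assay.
#' @param minMean,maxMean eligibility window on the per-gene mean of the
#'   log-normalized values.
#' @param nTop number of genes to return.
#' @param exclude character vector of gene names to drop from the result.
#' @param nBins number of equal-frequency mean bins for dispersion z-scoring.
#' @return character vector of selected gene names.
#' @export
selectHVG <- function(cells, minMean = 0.001, maxMean = 10, nTop = 7500,
                      exclude = character(), nBins = 20) {
    x <- expm1(assay(cells, "lognorm"))
    mu <- Matrix::rowSums(x) / ncol(x)
    ex2 <- Matrix::rowSums(x^2) / ncol(x)
    v <- (ex2 - mu^2) * ncol(x) / max(1, ncol(x) - 1)
    disp <- ifelse(mu > 0, v / mu, 0)
    eligible <- mu >= minMean & mu <= maxMean & disp > 0
    genes <- rownames(x)[eligible]
    if (!length(genes)) return(character())
    mu_e <- mu[eligible]; disp_e <- disp[eligible]
    nb <- max(1, min(nBins, length(genes)))
    bins <- cut(rank(mu_e, ties.method = "first"), breaks = nb, labels = FALSE)
    z <- disp_e
    for (b in unique(bins)) {
        i <- bins == b
        s <- stats::sd(disp_e[i])
        z[i] <- if (is.na(s) || s == 0) 0 else (disp_e[i] - mean(disp_e[i])) / s
    }
    ord <- genes[order(z, decreasing = TRUE)]
    ord <- setdiff(ord, exclude)
    if (nTop > length(ord)) {
        warning("fewer eligible genes than requested; returning all ",
                length(ord))
        return(ord)
    }
    ord[seq_len(nTop)]
}
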