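#' Write a cell dataset as MTX + TSV + CSV
#'
#' Serializes counts as Matrix Market (\code{matrix.mtx}) with
#' \code{barcodes.tsv} / \code{features.tsv}, per-cell metadata as
#' \code{obs.csv}, the embedding as \code{embedding.csv}, and any ground
#' truth as \code{ground_truth.json}.
#'
#' @param cells a \code{SingleCellExperiment}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
#' @importFrom utils write.csv write.table read.csv read.table head
writeCellDataset <- function(cells, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    m <- assay(cells, "counts")
    Matrix::writeMM(as(m, "CsparseMatrix"), file.path(dir, "matrix.mtx"))
    writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
    writeLines(rownames(m), file.path(dir, "features.tsv"))
    write.csv(as.data.frame(colData(cells)), file.path(dir, "obs.csv"),
              row.names = FALSE)
    emb <- SingleCellExperiment::reducedDim(cells, "embedding")
    write.csv(data.frame(cell_id = colnames(m), emb),
              file.path(dir, "embedding.csv"), row.names = FALSE)
    gt <- S4Vectors::metadata(cells)$ground_truth
    if (!is.null(gt))
        jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                             auto_unbox = TRUE, digits = NA, force = TRUE)
    invisible(dir)
}

#' Read a cell dataset written by [writeCellDataset()]
#'
#' @param dir directory holding matrix.mtx, barcodes.tsv, features.tsv,
#'   obs.csv and embedding.csv.
#' @return a \code{SingleCellExperiment}.
#' @export
readCellDataset <- function(dir) {
    m <- as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
    rownames(m) <- readLines(file.path(dir, "features.tsv"))
    colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
    obs <- read.csv(file.path(dir, "obs.csv"), stringsAsFactors = FALSE)
    sce <- SingleCellExperiment(
        assays = list(counts = m),
        colData = S4Vectors::DataFrame(obs, row.names = obs$cell_id))
    ef <- file.path(dir, "embedding.csv")
    if (file.exists(ef)) {
        emb <- read.csv(ef)
        SingleCellExperiment::reducedDim(sce, "embedding") <-
            as.matrix(emb[, -1, drop = FALSE])
    }
    sce
}

#' Write / read AIRR Rearrangement TSV
#'
#' Tab-separated with the standard AIRR column header; booleans are encoded
#' T/F as the AIRR spec allows.
#'
#' @param chains chain-record data.frame.
#' @param path file path.
#' @return \code{path} (write) or the chain data.frame (read).
#' @export
writeAIRR <- function(chains, path) {
    write.table(chains, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeAIRR
#' @export
readAIRR <- function(path) {
    read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write / read a spatial abundance CSV
#'
#' One row per spot: spot_id, x, y, slide_id, then one column per cell type.
#'
#' @param sa a \linkS4class{SpatialAbundance}.
#' @param path file path.
#' @return \code{path} (write) or a \code{SpatialAbundance} (read).
#' @export
writeSpatialAbundance <- function(sa, path) {
    df <- data.frame(spot_id = rownames(abundance(sa)),
                     spotCoords(sa), slide_id = slideId(sa),
                     abundance(sa), check.names = FALSE)
    write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeSpatialAbundance
#' @export
readSpatialAbundance <- function(path) {
    df <- read.csv(path, check.names = FALSE)
    A <- as.matrix(df[, setdiff(colnames(df),
                                c("spot_id", "x", "y", "slide_id")),
                   drop = FALSE])
    rownames(A) <- df$spot_id
    SpatialAbundance(A, as.matrix(df[, c("x", "y")]), df$slide_id)
}
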