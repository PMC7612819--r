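#' @import methods
#' @importFrom Matrix Matrix rowSums colSums t crossprod sparseMatrix
#' @importFrom Matrix Diagonal writeMM readMM
#' @importFrom SummarizedExperiment assay<- colData<-
#' @importFrom S4Vectors metadata metadata<-
#' @importFrom matrixStats colMedians rowMaxs
#' @importFrom jsonlite write_json
#' @importFrom stats median quantile var sd
#' @importClassesFrom Matrix dgCMatrix
NULL

#' NeighborhoodSet: index-cell neighborhoods on a KNN graph
#'
#' A set of neighborhoods over single cells, each anchored at a sampled and
#' refined index cell and containing that cell plus its neighbors on the
#' (union-symmetrized) KNN graph. The distance from each index cell to its
#' k-th nearest neighbor is kept because it later provides the weight for
#' the spatial FDR correction (denser neighborhoods get larger weights).
#'
#' @slot membership sparse 0/1 matrix, neighborhoods x cells.
#' @slot indexCells integer vector of index-cell column positions.
#' @slot kthDistance numeric vector, per-neighborhood distance from the index
#'   cell to its k-th nearest neighbor.
#' @slot cellIds character vector naming the columns of \code{membership}.
#' @slot k integer, the KNN graph degree used to build the set.
#'
#' @export
setClass("NeighborhoodSet",
    slots = c(
        membership  = "dgCMatrix",
        indexCells  = "integer",
        kthDistance = "numeric",
        cellIds     = "character",
        k           = "integer"
    )
)

setValidity("NeighborhoodSet", function(object) {
    m <- object@membership
    if (nrow(m) != length(object@indexCells))
        return("one index cell per neighborhood required")
    if (nrow(m) != length(object@kthDistance))
        return("one kthDistance per neighborhood required")
    if (ncol(m) != length(object@cellIds))
        return("cellIds must name the membership columns")
    if (any(!is.finite(object@kthDistance)) || any(object@kthDistance < 0))
        return("kthDistance must be finite and nonnegative")
    rs <- Matrix::rowSums(m)
    if (any(rs < 1))
        return("every neighborhood must contain at least one cell")
    idx <- cbind(seq_len(nrow(m)), object@indexCells)
    if (any(m[idx] == 0))
        return("every neighborhood must contain its own index cell")
    TRUE
})

#' SpatialAbundance: spot x cell-type abundances with coordinates
#'
#' Container for deconvolved cell-type abundance estimates on spatial
#' transcriptomics spots (e.g. the output of a deconvolution tool), across
#' one or more slides.
#'
#' @slot abundance nonnegative numeric matrix, spots x cell types.
#' @slot coords numeric matrix with columns x, y; one row per spot.
#' @slot slideId character vector, slide of origin per spot.
#' @slot groundTruth list; for synthetic data, the planted factors.
#'
#' @export
setClass("SpatialAbundance",
    slots = c(
        abundance   = "matrix",
        coords      = "matrix",
        slideId     = "character",
        groundTruth = "list"
    )
)

setValidity("SpatialAbundance", function(object) {
    a <- object@abundance
    if (any(a < 0)) return("abundances must be nonnegative")
    if (nrow(object@coords) != nrow(a) || ncol(object@coords) != 2L)
        return("coords must be a spots x 2 matrix")
    if (any(!is.finite(object@coords))) return("coordinates must be finite")
    if (length(object@slideId) != nrow(a))
        return("one slideId per spot required")
    if (is.null(colnames(a))) return("abundance needs cell-type column names")
    TRUE
})

#' MicroenvironmentSet: NMF factorization of spatial abundances
#'
#' Result of factorizing a spot x cell-type abundance matrix into d latent
#' microenvironments: spot weights W, factor loadings H, and the per-cell-type
#' loading fractions Hnorm (each cell type's loadings normalized to sum to 1
#' across factors), from which microenvironment membership is called.
#'
#' @slot W nonnegative matrix, spots x factors.
#' @slot H nonnegative matrix, factors x cell types.
#' @slot Hnorm matrix, factors x cell types; columns sum to 1.
#' @slot d integer factor count.
#' @slot membership list: per factor, the character vector of member cell
#'   types (filled by \code{microenvironmentMembership}).
#'
#' @export
setClass("MicroenvironmentSet",
    slots = c(
        W          = "matrix",
        H          = "matrix",
        Hnorm      = "matrix",
        d          = "integer",
        membership = "list"
    )
)

setValidity("MicroenvironmentSet", function(object) {
    if (any(object@W < 0) || any(object@H < 0))
        return("W and H must be nonnegative")
    if (ncol(object@W) != object@d || nrow(object@H) != object@d)
        return("W and H must have d factors")
    cs <- colSums(object@Hnorm)
    ok <- abs(cs - 1) < 1e-9 | cs == 0
    if (!all(ok)) return("Hnorm columns must sum to 1 (or 0 for absent types)")
    TRUE
})

setMethod("show", "NeighborhoodSet", function(object) {
    cat("NeighborhoodSet with", nrow(object@membership), "neighborhoods over",
        ncol(object@membership), "cells (k =", object@k, ")\n")
    sz <- Matrix::rowSums(object@membership)
    cat("  neighborhood sizes:", min(sz), "-", max(sz),
        "(median", stats::median(sz), ")\n")
})

setMethod("show", "SpatialAbundance", function(object) {
    cat("SpatialAbundance:", nrow(object@abundance), "spots x",
        ncol(object@abundance), "cell types on",
        length(unique(object@slideId)), "slide(s)\n")
})

setMethod("show", "MicroenvironmentSet", function(object) {
    cat("MicroenvironmentSet with d =", object@d, "factors over",
        ncol(object@H), "cell types;", nrow(object@W), "spots\n")
    if (length(object@membership))
        for (i in seq_along(object@membership))
            cat("  factor", i, ":",
                paste(object@membership[[i]], collapse = ", "), "\n")
})

## ---- accessors ----

#' @rdname NeighborhoodSet-class
#' @param x a \code{NeighborhoodSet}
#' @export
nhoodMembership <- function(x) x@membership

#' @rdname NeighborhoodSet-class
#' @export
indexCells <- function(x) x@indexCells

#' @rdname NeighborhoodSet-class
#' @export
kthDistance <- function(x) x@kthDistance

#' @rdname SpatialAbundance-class
#' @param x a \code{SpatialAbundance}
#' @export
abundance <- function(x) x@abundance

#' @rdname SpatialAbundance-class
#' @export
spotCoords <- function(x) x@coords

#' @rdname SpatialAbundance-class
#' @export
slideId <- function(x) x@slideId

#' @rdname MicroenvironmentSet-class
#' @param x a \code{MicroenvironmentSet}
#' @export
spotWeights <- function(x) x@W

#' @rdname MicroenvironmentSet-class
#' @export
factorLoadings <- function(x) x@H

#' @rdname MicroenvironmentSet-class
#' @export
loadingFractions <- function(x) x@Hnorm

#' Construct a SpatialAbundance object
#'
#' @param abundance spots x cell-type nonnegative matrix with column names.
#' @param coords spots x 2 matrix of x/y positions.
#' @param slideId character vector of slide identifiers, one per spot.
#' @param groundTruth optional list of planted truth (synthetic data).
#' @return a \code{SpatialAbundance}
#' @export
SpatialAbundance <- function(abundance, coords, slideId,
                             groundTruth = list()) {
    abundance <- as.matrix(abundance)
    coords <- as.matrix(coords)
    colnames(coords) <- c("x", "y")
    new("SpatialAbundance", abundance = abundance, coords = coords,
        slideId = as.character(slideId), groundTruth = groundTruth)
}
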