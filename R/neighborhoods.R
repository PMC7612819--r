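#' Build a KNN graph on an embedding
#'
#' Exact k-nearest-neighbor search under Euclidean distance, then
#' symmetrization by union (an edge is kept if either endpoint selects the
#' other). Ties at the k-th distance are broken by stable cell index. Degrees
#' k = 30 (gestational-age testing) and k = 100 (organ testing) are the
#' settings the atlas analysis uses.
#'
#' @param embedding numeric matrix, cells x latent dimensions.
#' @param k number of neighbors.
#' @return a list of class \code{knn_graph}: \code{index} and \code{distance}
#'   (cells x k matrices of neighbor indices / distances, ordered), and
#'   \code{adjacency}, the union-symmetrized sparse adjacency (no diagonal).
#' @export
#' @importFrom BiocNeighbors findKNN KmknnParam
buildKNN <- function(embedding, k) {
    embedding <- as.matrix(embedding)
    n <- nrow(embedding)
    if (k <= 0) stop("k must be positive")
    if (k >= n) stop("k must be smaller than the number of cells")
    if (any(!is.finite(embedding))) stop("embedding must be finite")
    nn <- BiocNeighbors::findKNN(embedding, k = k,
                                 BNPARAM = BiocNeighbors::KmknnParam())
    adj <- Matrix::sparseMatrix(
        i = rep(seq_len(n), k), j = as.vector(nn$index),
        x = 1, dims = c(n, n))
    adj <- adj + Matrix::t(adj)
    adj@x <- rep(1, length(adj@x))
    structure(list(index = nn$index, distance = nn$distance,
                   adjacency = adj, k = as.integer(k)),
              class = "knn_graph")
}

#' Sample and refine index-cell neighborhoods
#'
#' Samples \code{ceiling(prop * n)} index cells uniformly at random, refines
#' each to the member of its graph neighborhood closest to the neighborhood's
#' componentwise-median embedding position, deduplicates, and returns each
#' surviving index cell together with its (symmetrized) graph neighbors as a
#' neighborhood. The atlas setting is \code{prop = 0.05}.
#'
#' @param graph a \code{knn_graph} from [buildKNN()].
#' @param embedding the embedding the graph was built on.
#' @param prop fraction of cells to sample as index cells.
#' @param seed integer seed for the sampling step.
#' @return a \linkS4class{NeighborhoodSet}.
#' @export
makeNeighborhoods <- function(graph, embedding, prop = 0.05, seed = 42L) {
    stopifnot(inherits(graph, "knn_graph"), prop > 0, prop <= 1)
    embedding <- as.matrix(embedding)
    n <- nrow(embedding)
    nSample <- ceiling(prop * n)
    if (nSample < 1) stop("prop * n must be at least 1")
    set.seed(seed)
    sampled <- sample.int(n, nSample)
    adj <- as(graph$adjacency, "CsparseMatrix")
    ## adjacency is symmetric, so a cell's neighbors are its column entries
    colNbrs <- function(i) {
        if (adj@p[i + 1L] == adj@p[i]) integer() else
            adj@i[(adj@p[i] + 1L):adj@p[i + 1L]] + 1L
    }
    refined <- vapply(sampled, function(i) {
        members <- unique(c(i, colNbrs(i)))
        med <- matrixStats::colMedians(embedding[members, , drop = FALSE])
        d2 <- rowSums(sweep(embedding[members, , drop = FALSE], 2, med)^2)
        members[which.min(d2)]
    }, 0L)
    refined <- sort(unique(refined))
    memb <- Matrix::t(adj[, refined, drop = FALSE])
    diag_idx <- cbind(seq_along(refined), refined)
    memb[diag_idx] <- 1
    cellIds <- if (!is.null(rownames(embedding))) rownames(embedding) else
        as.character(seq_len(n))
    kth <- graph$distance[refined, graph$k]
    new("NeighborhoodSet", membership = as(memb, "CsparseMatrix"),
        indexCells = as.integer(refined), kthDistance = as.numeric(kth),
        cellIds = cellIds, k = graph$k)
}

#' Count cells per sample in each neighborhood
#'
#' @param nhoods a \linkS4class{NeighborhoodSet}.
#' @param cells the \code{SingleCellExperiment} the neighborhoods were built
#'   on (same cell order); \code{colData} must carry \code{sample_id} plus
#'   the per-sample covariates (donor_id, organ, age_pcw, sort_fraction).
#' @param samples optional character vector fixing the sample (column) set;
#'   samples absent from \code{cells} yield zero columns with a warning.
#' @return a \code{SummarizedExperiment}: assay \code{"counts"}
#'   (neighborhoods x samples, integer), \code{colData} with one row of
#'   sample metadata per sample, \code{rowData} with the index cell and
#'   k-th-NN distance per neighborhood.
#' @export
#' @importFrom SummarizedExperiment SummarizedExperiment
countCellsBySample <- function(nhoods, cells, samples = NULL) {
    cd <- as.data.frame(colData(cells))
    if (is.null(cd$sample_id)) stop("cells must carry a sample_id column")
    if (ncol(nhoodMembership(nhoods)) != nrow(cd))
        stop("neighborhoods and cells disagree on cell number")
    found <- unique(cd$sample_id)
    if (is.null(samples)) samples <- found
    if (length(setdiff(samples, found)))
        warning("samples absent from cells get zero columns: ",
                paste(setdiff(samples, found), collapse = ", "))
    ind <- Matrix::sparseMatrix(
        i = seq_len(nrow(cd)),
        j = match(cd$sample_id, samples),
        x = 1, dims = c(nrow(cd), length(samples)))
    counts <- as.matrix(nhoodMembership(nhoods) %*% ind)
    storage.mode(counts) <- "integer"
    colnames(counts) <- samples
    rownames(counts) <- paste0("nhood", seq_len(nrow(counts)))
    keep <- c("sample_id", "donor_id", "organ", "age_pcw", "sort_fraction")
    keep <- intersect(keep, colnames(cd))
    meta <- unique(cd[, keep, drop = FALSE])
    meta <- meta[match(samples, meta$sample_id), , drop = FALSE]
    meta$sample_id <- samples
    rownames(meta) <- samples
    SummarizedExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(meta),
        rowData = S4Vectors::DataFrame(
            index_cell = indexCells(nhoods),
            kth_nn_distance = kthDistance(nhoods)))
}

#' Label neighborhoods by majority vote
#'
#' A neighborhood is labeled with its modal member cell-type label when that
#' label covers more than 50% of member cells; otherwise it is labeled
#' \code{"Mixed"}. The atlas rule assigns Mixed when the most abundant label
#' is below 50%; an exact-50% share (including a 50/50 tie) is also treated
#' as Mixed here, which is the conservative deterministic reading of the
#' boundary.
#'
#' @param nhoods a \linkS4class{NeighborhoodSet}.
#' @param cellLabels character vector of per-cell labels (membership column
#'   order).
#' @return character vector of neighborhood labels.
#' @export
labelNeighborhoods <- function(nhoods, cellLabels) {
    m <- nhoodMembership(nhoods)
    if (length(cellLabels) != ncol(m))
        stop("one label per cell required")
    if (anyNA(cellLabels)) stop("all member cells must be labeled")
    labs <- factor(cellLabels)
    ind <- Matrix::sparseMatrix(i = seq_along(labs),
                                j = as.integer(labs), x = 1,
                                dims = c(length(labs), nlevels(labs)))
    tab <- as.matrix(m %*% ind)
    colnames(tab) <- levels(labs)
    tot <- rowSums(tab)
    if (any(tot == 0)) stop("empty neighborhood")
    mx <- matrixStats::rowMaxs(tab)
    modal <- colnames(tab)[max.col(tab, ties.method = "first")]
    ifelse(mx / tot > 0.5, modal, "Mixed")
}

#' Per-sample FACS correction factor
#'
#' FACS-sorted libraries over- or under-represent their gate's cells relative
#' to the dissociation they came from. The correction covariate used in
#' differential-abundance models is the natural log of the measured live-cell
#' proportion of the sample's sort gate; unsorted samples get 0.
#'
#' @param sampleMeta data.frame with \code{sample_id} and
#'   \code{sort_fraction} (\code{"unsorted"}, \code{"CD45pos"},
#'   \code{"CD45neg"}).
#' @param facsProportions named numeric vector: measured live-cell proportion
#'   of the gate, named by sample_id, for every sorted sample.
#' @return named numeric vector of per-sample correction factors.
#' @export
facsCorrectionFactor <- function(sampleMeta, facsProportions = numeric()) {
    out <- stats::setNames(numeric(nrow(sampleMeta)), sampleMeta$sample_id)
    sorted <- sampleMeta$sort_fraction != "unsorted"
    if (any(sorted)) {
        sid <- sampleMeta$sample_id[sorted]
        missing <- sid[!sid %in% names(facsProportions)]
        if (length(missing))
            stop("sorted sample(s) without a measured proportion: ",
                 paste(missing, collapse = ", "))
        pi <- facsProportions[sid]
        if (any(pi <= 0 | pi > 1)) stop("proportions must lie in (0, 1]")
        out[sid] <- log(pi)
    }
    out
}
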