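#' Gaussian-kernel KNN label transfer in a joint embedding
#'
#' For each query cell, the k nearest reference cells (Euclidean distance in
#' the shared embedding) vote for their labels with Gaussian weights
#' \code{exp(-d^2 / (2 sigma^2))}, where the bandwidth sigma is the query
#' cell's distance to its k-th reference neighbor (adaptive: tight in dense
#' regions, wide in sparse ones). Per-label scores are the weight sums
#' normalized to 1; the prediction is the argmax.
#'
#' @param queryEmbedding,refEmbedding matrices with matching column count.
#' @param refLabels character vector, one label per reference cell.
#' @param k number of reference neighbors (default 30, matching the
#'   embedding-graph degree).
#' @return list: \code{predicted} (per-query label), \code{scores}
#'   (query x label matrix, rows sum to 1), \code{nnDist} (distance to the
#'   nearest reference cell).
#' @export
#' @importFrom BiocNeighbors queryKNN
knnGaussianLabelTransfer <- function(queryEmbedding, refEmbedding,
                                     refLabels, k = 30) {
    queryEmbedding <- as.matrix(queryEmbedding)
    refEmbedding <- as.matrix(refEmbedding)
    if (ncol(queryEmbedding) != ncol(refEmbedding))
        stop("query and reference embeddings differ in dimensionality")
    if (nrow(refEmbedding) == 0) stop("empty reference")
    if (k <= 0) stop("k must be positive")
    if (k > nrow(refEmbedding)) stop("k exceeds the reference size")
    if (length(refLabels) != nrow(refEmbedding))
        stop("one label per reference cell required")
    nn <- BiocNeighbors::queryKNN(refEmbedding, queryEmbedding, k = k,
                                  BNPARAM = BiocNeighbors::KmknnParam())
    sigma <- nn$distance[, k]
    sigma[sigma == 0] <- .Machine$double.eps
    w <- exp(-nn$distance^2 / (2 * sigma^2))
    labs <- factor(refLabels)
    nQ <- nrow(queryEmbedding)
    scores <- matrix(0, nQ, nlevels(labs),
                     dimnames = list(rownames(queryEmbedding), levels(labs)))
    for (j in seq_len(k)) {
        lj <- as.integer(labs)[nn$index[, j]]
        scores[cbind(seq_len(nQ), lj)] <-
            scores[cbind(seq_len(nQ), lj)] + w[, j]
    }
    scores <- scores / rowSums(scores)
    list(predicted = levels(labs)[max.col(scores, ties.method = "first")],
         scores = scores, nnDist = nn$distance[, 1])
}

#' Normalized mutual information between two labelings
#'
#' NMI = I(A;B) normalized by the mean of the two label entropies
#' (arithmetic by default; geometric available). Invariant to label
#' renaming; 1 for identical partitions. When either labeling has a single
#' class the quantity is 0/0 and 0 is returned with a warning.
#'
#' @param a,b equal-length label vectors.
#' @param normalization \code{"arithmetic"} (default) or \code{"geometric"}
#'   mean of the entropies.
#' @return NMI in [0, 1].
#' @export
nmiScore <- function(a, b, normalization = c("arithmetic", "geometric")) {
    normalization <- match.arg(normalization)
    if (length(a) != length(b)) stop("labelings differ in length")
    if (!length(a)) stop("empty labelings")
    tab <- table(a, b)
    n <- sum(tab)
    pij <- tab / n
    pi_ <- rowSums(pij); pj_ <- colSums(pij)
    Ha <- -sum(ifelse(pi_ > 0, pi_ * log(pi_), 0))
    Hb <- -sum(ifelse(pj_ > 0, pj_ * log(pj_), 0))
    if (Ha == 0 || Hb == 0) {
        warning("single-class labeling: NMI undefined, returning 0")
        return(0)
    }
    E <- outer(pi_, pj_)
    pos <- pij > 0
    I <- sum(pij[pos] * log(pij[pos] / E[pos]))
    denom <- if (normalization == "arithmetic") (Ha + Hb) / 2 else
        sqrt(Ha * Hb)
    min(1, max(0, I / denom))
}
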