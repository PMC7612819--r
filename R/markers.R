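#' Split a cell type's cells by differential-abundance direction
#'
#' After age DA testing, marker discovery contrasts the cells of
#' direction-specific significant neighborhoods against the cells of all
#' other neighborhoods carrying the same cell-type label. Early-specific
#' neighborhoods are SpatialFDR < 0.1 with logFC < 0; late-specific ones
#' SpatialFDR < 0.1 with logFC > 0. A cell that belongs to both a
#' significant and a non-significant neighborhood is assigned to the
#' significant set only, keeping the two groups disjoint.
#'
#' @param da a \code{DAResult} data.frame with \code{label}, \code{logFC},
#'   \code{spatial_fdr} (neighborhood order matching \code{nhoods}).
#' @param nhoods the \linkS4class{NeighborhoodSet} that was tested.
#' @param celltype neighborhood label to analyze.
#' @param direction \code{"early"} or \code{"late"}.
#' @param fdrThreshold significance cut on spatial FDR (default 0.1).
#' @return list with integer cell indices \code{setA} (significant,
#'   direction-specific) and \code{setB} (other neighborhoods of the type).
#' @export
selectDACells <- function(da, nhoods, celltype,
                          direction = c("early", "late"),
                          fdrThreshold = 0.1) {
    direction <- match.arg(direction)
    m <- nhoodMembership(nhoods)
    if (nrow(da) != nrow(m)) stop("da and nhoods disagree on neighborhoods")
    ofType <- !is.na(da$label) & da$label == celltype
    sig <- ofType & !is.na(da$spatial_fdr) & da$spatial_fdr < fdrThreshold &
        (if (direction == "early") da$logFC < 0 else da$logFC > 0)
    other <- ofType & !sig
    cellsIn <- function(rows) {
        if (!any(rows)) return(integer())
        which(Matrix::colSums(m[rows, , drop = FALSE]) > 0)
    }
    setA <- cellsIn(sig)
    if (!length(setA))
        warning("no significant ", direction, "-specific neighborhoods for ",
                celltype)
    setB <- setdiff(cellsIn(other), setA)
    list(setA = setA, setB = setB)
}

#' Two-group gene ranking with the overestimated-variance t-test
#'
#' Per-gene comparison of log-normalized expression between two cell sets
#' using the t statistic \code{(mA - mB) / sqrt(vA/nA + vB/nA)} - the
#' "overestimated variance" variant in which the first group's size is used
#' in both variance terms, making the test deliberately conservative for the
#' (typically smaller) group of interest. Degrees of freedom follow
#' Welch-Satterthwaite with the same substitution; p-values are two-sided
#' with BH-adjusted FDR. The reported logFC is the natural log of the ratio
#' of back-transformed group means, \code{log(expm1(mA) / expm1(mB))} with a
#' small pseudocount: this undoes the compression of the log1p transform, so
#' a gene whose expression rises e-fold reports a logFC near 1 regardless of
#' its expression level (the convention of the scanpy ranking the atlas
#' used).
#'
#' @param normExpr genes x cells matrix of log-normalized expression.
#' @param setA,setB disjoint cell index vectors (|A| >= 2, |B| >= 2).
#' @return \code{DEResult} data.frame: gene, logFC, t, pval, FDR,
#'   expr_fraction (fraction of tested cells with nonzero expression).
#' @export
rankGenesWelchT <- function(normExpr, setA, setB) {
    if (length(setA) < 2 || length(setB) < 2)
        stop("both cell sets need at least two cells")
    A <- normExpr[, setA, drop = FALSE]
    B <- normExpr[, setB, drop = FALSE]
    nA <- ncol(A); nB <- ncol(B)
    mA <- Matrix::rowSums(A) / nA
    mB <- Matrix::rowSums(B) / nB
    vA <- (Matrix::rowSums(A^2) / nA - mA^2) * nA / (nA - 1)
    vB <- (Matrix::rowSums(B^2) / nB - mB^2) * nB / (nB - 1)
    vA <- pmax(vA, 0); vB <- pmax(vB, 0)
    se2 <- vA / nA + vB / nA
    t <- ifelse(se2 > 0, (mA - mB) / sqrt(se2), 0)
    df <- ifelse(se2 > 0,
                 (nA - 1) * (vA + vB)^2 / pmax(vA^2 + vB^2, .Machine$double.xmin),
                 1)
    p <- ifelse(se2 > 0, 2 * stats::pt(-abs(t), df), 1)
    tested <- cbind(A, B)
    frac <- Matrix::rowSums(tested > 0) / (nA + nB)
    eps <- 1e-9
    lfc <- log((expm1(mA) + eps) / (expm1(mB) + eps))
    data.frame(gene = rownames(normExpr), logFC = lfc, t = t,
               pval = p, FDR = stats::p.adjust(p, "BH"),
               expr_fraction = frac, row.names = NULL)
}

#' Apply the atlas marker filter chain
#'
#' A gene is reported as a marker when it is expressed in at most 70% of the
#' tested cells (broadly expressed genes are excluded), its logFC exceeds 1
#' (natural log), and its FDR is below 0.1%.
#'
#' @param de a \code{DEResult} from [rankGenesWelchT()].
#' @param maxExprFraction exclusion threshold on expressed fraction (0.7).
#' @param lfcThreshold minimum logFC (1).
#' @param fdrThreshold maximum FDR (0.001).
#' @return the marker subset of \code{de}, ordered by FDR.
#' @export
filterMarkers <- function(de, maxExprFraction = 0.7, lfcThreshold = 1,
                          fdrThreshold = 0.001) {
    keep <- de$expr_fraction <= maxExprFraction &
        de$logFC > lfcThreshold & de$FDR < fdrThreshold
    out <- de[keep, , drop = FALSE]
    out[order(out$FDR), , drop = FALSE]
}

#' Score cells for a gene set against expression-matched controls
#'
#' Per-cell activation score: the mean log-normalized expression of the set
#' genes minus the mean of a control pool drawn from expression-matched
#' genes. All genes are cut into \code{nBins} equal-size bins of average
#' expression and, for each set gene, \code{nControl} control genes are
#' sampled from its bin (set genes excluded), so the control matches the
#' set's expression profile. Set genes missing from the matrix are dropped
#' with a message.
#'
#' @param normExpr genes x cells matrix of log-normalized expression.
#' @param geneSet character vector of set gene names.
#' @param nBins number of expression bins (default 25).
#' @param nControl control genes sampled per set gene (default 50).
#' @param seed integer; fixes the control sampling.
#' @return named numeric vector of per-cell scores.
#' @export
scoreGeneSet <- function(normExpr, geneSet, nBins = 25, nControl = 50,
                         seed = 0L) {
    present <- intersect(geneSet, rownames(normExpr))
    dropped <- setdiff(geneSet, present)
    if (length(dropped))
        message(length(dropped), " set gene(s) not present were dropped")
    if (!length(present)) stop("gene set empty after intersection")
    set.seed(seed)
    avg <- Matrix::rowSums(normExpr) / ncol(normExpr)
    nb <- max(1, min(nBins, nrow(normExpr) %/% 2))
    bins <- if (nb >= 2)
        cut(rank(avg, ties.method = "first"), breaks = nb, labels = FALSE)
    else rep(1L, nrow(normExpr))
    names(bins) <- rownames(normExpr)
    ctrl <- character()
    for (g in present) {
        pool <- setdiff(names(bins)[bins == bins[g]], geneSet)
        if (!length(pool)) next
        ctrl <- c(ctrl, sample(pool, min(nControl, length(pool))))
    }
    ctrl <- unique(ctrl)
    setMean <- Matrix::colSums(normExpr[present, , drop = FALSE]) /
        length(present)
    ctrlMean <- if (length(ctrl))
        Matrix::colSums(normExpr[ctrl, , drop = FALSE]) / length(ctrl)
    else 0
    score <- setMean - ctrlMean
    stats::setNames(as.numeric(score), colnames(normExpr))
}
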