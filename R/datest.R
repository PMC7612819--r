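#' Bin gestational ages and drop sparsely profiled organs
#'
#' Samples are binned into equal-width gestational-age bins (width 2 pcw in
#' the atlas analysis, giving six bins over 7-17 pcw), anchored at the
#' minimum age in the dataset. Organs whose samples never span at least
#' three consecutive occupied bins are excluded from age testing, because a
#' trend cannot be distinguished from an organ-collection artifact there.
#'
#' @param sampleMeta data.frame with \code{age_pcw} and \code{organ}.
#' @param binWidth bin width in pcw.
#' @return list: \code{meta} (input plus integer \code{age_bin}, restricted
#'   to retained organs), \code{bins} (break points), \code{retainedOrgans},
#'   \code{excludedOrgans}.
#' @export
binGestationalAges <- function(sampleMeta, binWidth = 2) {
    stopifnot(all(sampleMeta$age_pcw > 0), binWidth > 0)
    a0 <- min(sampleMeta$age_pcw)
    bin <- as.integer(floor((sampleMeta$age_pcw - a0) / binWidth)) + 1L
    maxRun <- function(b) {
        occ <- sort(unique(b))
        if (length(occ) == 1L) return(1L)
        r <- rle(diff(occ) == 1L)
        1L + max(c(0L, r$lengths[r$values]))
    }
    runs <- tapply(bin, sampleMeta$organ, maxRun)
    retained <- names(runs)[runs >= 3L]
    excluded <- setdiff(names(runs), retained)
    if (!length(retained)) stop("no organ spans three consecutive age bins")
    keep <- sampleMeta$organ %in% retained
    meta <- sampleMeta[keep, , drop = FALSE]
    meta$age_bin <- bin[keep]
    nb <- max(bin)
    list(meta = meta,
         bins = a0 + binWidth * (0:nb),
         retainedOrgans = retained, excludedOrgans = excluded)
}

## Build a full-rank model matrix from a formula over the sample metadata:
## constant non-intercept columns (e.g. an all-zero FACS factor in an
## unsorted dataset) and aliased columns are dropped, so including an
## uninformative covariate leaves the fit untouched.
.daModelMatrix <- function(design, data) {
    mm <- stats::model.matrix(design, data = data)
    keep <- colnames(mm) == "(Intercept)" |
        apply(mm, 2, function(x) stats::var(x) > 0)
    mm <- mm[, keep, drop = FALSE]
    qr_ <- qr(mm)
    if (qr_$rank < ncol(mm))
        mm <- mm[, qr_$pivot[seq_len(qr_$rank)], drop = FALSE]
    mm
}

#' Fit per-neighborhood negative-binomial GLMs on cell counts
#'
#' Models the neighborhood x sample cell counts with a log-linear
#' negative-binomial GLM, using the total cells per sample over all
#' neighborhoods as the offset, dispersion shrunk toward a mean-dispersion
#' trend, and a quasi-likelihood F-test for the contrast of interest
#' (the edgeR estimation route). Coefficients are reported as natural-log
#' fold changes.
#'
#' @param counts a \code{SummarizedExperiment} from [countCellsBySample()]
#'   (or any integer neighborhoods x samples matrix inside one), with sample
#'   covariates in \code{colData}.
#' @param design a one-sided formula over \code{colData(counts)}, e.g.
#'   \code{~ facs_factor + age_bin}.
#' @param coef name (or index) of the model coefficient to test.
#' @return data.frame, one row per input neighborhood in input order:
#'   \code{nhood_id}, \code{logFC} (natural log), \code{pval}; neighborhoods
#'   with all-zero counts are reported as NA rows and listed in
#'   \code{attr(x, "dropped")}.
#' @export
#' @importFrom edgeR DGEList estimateDisp glmQLFit glmQLFTest
fitNhoodGLM <- function(counts, design, coef) {
    y <- assay(counts, "counts")
    if (is.null(rownames(y)))
        rownames(y) <- paste0("nhood", seq_len(nrow(y)))
    meta <- as.data.frame(colData(counts))
    tot <- colSums(y)
    if (any(tot == 0)) {
        warning("dropping sample(s) with zero cells in all neighborhoods: ",
                paste(colnames(y)[tot == 0], collapse = ", "))
        y <- y[, tot > 0, drop = FALSE]
        meta <- meta[tot > 0, , drop = FALSE]
        tot <- tot[tot > 0]
    }
    mm <- .daModelMatrix(design, meta)
    if (is.character(coef) && !coef %in% colnames(mm))
        stop("coefficient '", coef, "' not in the (pruned) design: ",
             paste(colnames(mm), collapse = ", "))
    nonzero <- rowSums(y) > 0
    dge <- edgeR::DGEList(counts = y[nonzero, , drop = FALSE],
                          lib.size = tot)
    dge <- edgeR::estimateDisp(dge, mm)
    fit <- edgeR::glmQLFit(dge, mm, robust = TRUE)
    test <- edgeR::glmQLFTest(fit, coef = coef)
    out <- data.frame(nhood_id = rownames(y),
                      logFC = NA_real_, pval = NA_real_)
    out$logFC[nonzero] <- test$table$logFC * log(2)
    out$pval[nonzero] <- test$table$PValue
    attr(out, "dropped") <- rownames(y)[!nonzero]
    attr(out, "design") <- mm
    out
}

#' Weighted Benjamini-Hochberg spatial FDR over neighborhoods
#'
#' Neighborhoods overlap, so a plain BH correction over-counts effective
#' tests in dense regions. Each neighborhood is weighted by the reciprocal
#' of its index cell's k-th-nearest-neighbor distance (dense neighborhoods
#' get large weights): after sorting by p, the adjusted value is
#' \code{min over j >= i of p_(j) * sum(w) / cumsum(w)_(j)}, clipped to
#' [0, 1] and returned in input order. With constant weights this reduces
#' exactly to standard BH.
#'
#' @param pvalues numeric vector of per-neighborhood p-values (NA allowed
#'   for untested neighborhoods; they are ignored and returned as NA).
#' @param kthDist positive distances to each neighborhood's k-th neighbor.
#' @return numeric vector of spatial-FDR-adjusted values, input order.
#' @export
spatialFDR <- function(pvalues, kthDist) {
    if (length(pvalues) != length(kthDist))
        stop("pvalues and kthDist must have equal length")
    ok <- !is.na(pvalues)
    if (any(kthDist[ok] <= 0)) stop("kth-NN distance must be positive")
    p <- pvalues[ok]
    w <- 1 / kthDist[ok]
    o <- order(p)
    q <- p[o] * sum(w) / cumsum(w[o])
    q <- rev(cummin(rev(q)))
    q <- pmin(q, 1)
    out <- rep(NA_real_, length(pvalues))
    out[ok][o] <- q
    out
}

#' Differential abundance across gestational age
#'
#' End-to-end age test: bins sample ages ([binGestationalAges()]), drops
#' organs without three consecutive occupied bins, fits the per-neighborhood
#' NB GLM with the age bin as an ordinal linear covariate while accounting
#' for the FACS correction factor (and any further confounders), and applies
#' the weighted spatial FDR. Positive logFC means enrichment later in
#' gestation.
#'
#' @param counts \code{SummarizedExperiment} from [countCellsBySample()];
#'   \code{colData} needs \code{age_pcw}, \code{organ}, and any confounders;
#'   \code{rowData} needs \code{kth_nn_distance}.
#' @param binWidth age bin width in pcw (default 2).
#' @param confounders character vector of colData covariates to adjust for
#'   (default \code{"facs_factor"} if present).
#' @param labels optional per-neighborhood labels to carry through.
#' @param ageCoding \code{"ordinal"} (single linear slope per bin index, the
#'   default) or \code{"categorical"} (bins as factor levels; the reported
#'   logFC is the last-vs-first bin contrast scaled to a per-bin step).
#' @return a \code{DAResult} data.frame: nhood_id, label, logFC, pval,
#'   spatial_fdr; excluded organs recorded in \code{attr(x, "excludedOrgans")}.
#' @export
testGestationalAge <- function(counts, binWidth = 2, confounders = NULL,
                               labels = NULL,
                               ageCoding = c("ordinal", "categorical")) {
    ageCoding <- match.arg(ageCoding)
    meta <- as.data.frame(colData(counts))
    if (is.null(confounders))
        confounders <- intersect("facs_factor", colnames(meta))
    binned <- binGestationalAges(meta, binWidth)
    keep <- meta$sample_id %in% binned$meta$sample_id
    sub <- counts[, keep]
    meta <- binned$meta[match(colData(sub)$sample_id, binned$meta$sample_id), ]
    SummarizedExperiment::colData(sub)$age_bin <- meta$age_bin
    rhs <- paste(c(confounders,
                   if (ageCoding == "ordinal") "age_bin"
                   else "factor(age_bin)"), collapse = " + ")
    des <- stats::as.formula(paste("~", rhs))
    if (ageCoding == "ordinal") {
        fitres <- fitNhoodGLM(sub, des, coef = "age_bin")
    } else {
        mmNames <- colnames(.daModelMatrix(des, as.data.frame(colData(sub))))
        lastBin <- mmNames[grepl("^factor\\(age_bin\\)", mmNames)]
        lastBin <- lastBin[length(lastBin)]
        fitres <- fitNhoodGLM(sub, des, coef = lastBin)
        nb <- length(unique(meta$age_bin))
        fitres$logFC <- fitres$logFC / max(1, nb - 1)
    }
    res <- data.frame(nhood_id = fitres$nhood_id,
                      label = if (is.null(labels)) NA_character_ else labels,
                      logFC = fitres$logFC, pval = fitres$pval)
    res$spatial_fdr <- spatialFDR(res$pval,
                                  SummarizedExperiment::rowData(counts)$kth_nn_distance)
    attr(res, "excludedOrgans") <- binned$excludedOrgans
    res
}

#' Test neighborhoods for organ-specific enrichment
#'
#' Fits the per-neighborhood NB GLM with a target-organ-vs-rest indicator
#' while accounting for the FACS correction factor and library protocol,
#' then flags neighborhoods with a positive organ coefficient and
#' SpatialFDR < 0.01 as organ-enriched subpopulations.
#'
#' @param counts as in [testGestationalAge()].
#' @param targetOrgan organ code to contrast against all others.
#' @param confounders colData covariates to adjust for (default
#'   \code{facs_factor} and \code{protocol} where present).
#' @param labels optional per-neighborhood labels.
#' @param fdrThreshold,lfcThreshold flagging rule (defaults 0.01 and 0).
#' @return a \code{DAResult} data.frame with an extra logical \code{flagged}
#'   column.
#' @export
testOrganSpecificity <- function(counts, targetOrgan, confounders = NULL,
                                 labels = NULL, fdrThreshold = 0.01,
                                 lfcThreshold = 0) {
    meta <- as.data.frame(colData(counts))
    if (length(unique(meta$organ)) < 2L)
        stop("organ testing needs at least two organs")
    if (sum(meta$organ == targetOrgan) < 2L)
        stop("target organ must be present in at least two samples")
    if (is.null(confounders))
        confounders <- intersect(c("facs_factor", "protocol"), colnames(meta))
    SummarizedExperiment::colData(counts)$is_target <-
        as.numeric(meta$organ == targetOrgan)
    des <- stats::as.formula(
        paste("~", paste(c(confounders, "is_target"), collapse = " + ")))
    fitres <- fitNhoodGLM(counts, des, coef = "is_target")
    res <- data.frame(nhood_id = fitres$nhood_id,
                      label = if (is.null(labels)) NA_character_ else labels,
                      logFC = fitres$logFC, pval = fitres$pval)
    res$spatial_fdr <- spatialFDR(res$pval,
                                  SummarizedExperiment::rowData(counts)$kth_nn_distance)
    res$flagged <- !is.na(res$spatial_fdr) &
        res$logFC > lfcThreshold & res$spatial_fdr < fdrThreshold
    res
}
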