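#' Aggregate single cells into pseudobulk profiles
#'
#' Sums raw counts over all cells of each (sample, cell type) group with at
#' least \code{minCells} cells, yielding one bulk-like column per group.
#' Library size is the column total; groups below the cell threshold are
#' dropped and reported.
#'
#' @param cells a \code{SingleCellExperiment} with raw \code{"counts"} and
#'   colData columns \code{sample_id}, \code{celltype_label},
#'   \code{donor_id}, \code{organ}.
#' @param minCells minimum cells per pseudobulk (default 20, matching the
#'   atlas' minimum population sizes elsewhere).
#' @return a \code{SummarizedExperiment}: assay \code{"counts"} (genes x
#'   pseudobulks), colData with donor, organ, celltype, n_cells, lib_size;
#'   dropped groups in \code{metadata(x)$dropped}.
#' @export
aggregatePseudobulk <- function(cells, minCells = 20) {
    cd <- as.data.frame(colData(cells))
    grp <- paste(cd$sample_id, cd$celltype_label, sep = ".")
    counts <- assay(cells, "counts")
    ug <- unique(grp)
    sizes <- table(grp)[ug]
    ind <- Matrix::sparseMatrix(i = seq_along(grp),
                                j = match(grp, ug), x = 1,
                                dims = c(length(grp), length(ug)))
    agg <- as.matrix(counts %*% ind)
    colnames(agg) <- ug
    keep <- as.integer(sizes) >= minCells
    if (!any(keep)) stop("no (sample, celltype) group reaches minCells")
    first <- match(ug, grp)
    meta <- data.frame(
        pseudobulk_id = ug,
        sample_id = cd$sample_id[first],
        donor_id = cd$donor_id[first],
        organ = cd$organ[first],
        celltype = cd$celltype_label[first],
        n_cells = as.integer(sizes),
        row.names = ug)
    agg <- agg[, keep, drop = FALSE]
    meta <- meta[keep, , drop = FALSE]
    meta$lib_size <- colSums(agg)
    storage.mode(agg) <- "integer"
    se <- SummarizedExperiment(assays = list(counts = agg),
                               colData = S4Vectors::DataFrame(meta))
    S4Vectors::metadata(se)$dropped <- ug[!keep]
    se
}

#' Organ x cell-type interaction differential expression on pseudobulks
#'
#' Per gene, pseudobulk counts are modeled as negative binomial with
#' log-linear mean: intercept, donor effects, a target-organ indicator, a
#' target-cell-type indicator, their interaction, and the log library size
#' as offset. The interaction coefficient is the organ-specific expression
#' change in the target cell type over and above organ-wide and type-wide
#' shifts; it is estimated and tested with the quasi-likelihood method and
#' reported in natural log with BH FDR.
#'
#' @param pb a pseudobulk \code{SummarizedExperiment} from
#'   [aggregatePseudobulk()].
#' @param targetOrgan,targetCelltype levels defining the interaction.
#' @return \code{InteractionFit} data.frame: gene, logFC (interaction,
#'   natural log), pval, FDR, dispersion, converged.
#' @export
fitInteractionNBGLM <- function(pb, targetOrgan, targetCelltype) {
    meta <- as.data.frame(colData(pb))
    if (length(unique(meta$donor_id)) < 2L) stop("need at least two donors")
    if (!targetOrgan %in% meta$organ) stop("target organ absent")
    if (!targetCelltype %in% meta$celltype) stop("target cell type absent")
    if (length(unique(meta$organ)) < 2L ||
        length(unique(meta$celltype)) < 2L)
        stop("interaction needs >= 2 organs and >= 2 cell types")
    meta$o <- as.numeric(meta$organ == targetOrgan)
    meta$c <- as.numeric(meta$celltype == targetCelltype)
    mm <- .daModelMatrix(~ donor_id + o + c + o:c, meta)
    if (!"o:c" %in% colnames(mm))
        stop("interaction term aliased: target organ/celltype combination ",
             "not identifiable in this design")
    y <- assay(pb, "counts")
    dge <- edgeR::DGEList(counts = y, lib.size = meta$lib_size)
    dge <- edgeR::estimateDisp(dge, mm)
    fit <- edgeR::glmQLFit(dge, mm, robust = TRUE)
    test <- edgeR::glmQLFTest(fit, coef = "o:c")
    data.frame(gene = rownames(y),
               logFC = test$table$logFC * log(2),
               pval = test$table$PValue,
               FDR = stats::p.adjust(test$table$PValue, "BH"),
               dispersion = dge$tagwise.dispersion,
               converged = !fit$failed,
               row.names = NULL)
}

#' Per-cell-type organ differential expression on pseudobulks
#'
#' Restricts the pseudobulk matrix to one cell type and fits, per gene, the
#' NB GLM \code{log mu = b0 + donor + organ-indicator + log L_p} with the
#' quasi-likelihood test on the organ indicator. This is the within-cell-type
#' organ logFC used by the control-cell-type technical filter: a gene driven
#' by tissue processing shows the same organ effect in control cell types,
#' where no organ-specific biology is expected, and a pure interaction
#' coefficient would be blind to such uniform technical shifts.
#'
#' @param pb a pseudobulk \code{SummarizedExperiment}.
#' @param targetOrgan organ contrasted against all others.
#' @param celltype cell type whose pseudobulks are analyzed.
#' @return data.frame: gene, logFC (natural log), pval, FDR.
#' @export
fitOrganDE <- function(pb, targetOrgan, celltype) {
    meta <- as.data.frame(colData(pb))
    keep <- meta$celltype == celltype
    if (sum(keep) < 4L) stop("too few pseudobulks for cell type ", celltype)
    meta <- meta[keep, , drop = FALSE]
    if (!targetOrgan %in% meta$organ)
        stop("target organ absent for cell type ", celltype)
    if (length(unique(meta$organ)) < 2L) stop("single-organ pseudobulks")
    meta$o <- as.numeric(meta$organ == targetOrgan)
    mm <- .daModelMatrix(~ donor_id + o, meta)
    y <- assay(pb, "counts")[, keep, drop = FALSE]
    dge <- edgeR::DGEList(counts = y, lib.size = meta$lib_size)
    dge <- edgeR::estimateDisp(dge, mm)
    fit <- edgeR::glmQLFit(dge, mm, robust = TRUE)
    test <- edgeR::glmQLFTest(fit, coef = "o")
    data.frame(gene = rownames(y),
               logFC = test$table$logFC * log(2),
               pval = test$table$PValue,
               FDR = stats::p.adjust(test$table$PValue, "BH"),
               row.names = NULL)
}

#' Filter interaction hits by control cell types
#'
#' Organ differences in a cell type can be driven by tissue processing
#' rather than biology. The same organ contrast is fitted on control cell
#' types where no organ-specific biology is expected; a gene is flagged as
#' technical and removed when any control fit shows a same-sign logFC of at
#' least \code{lfcThreshold} at FDR < \code{fdrThreshold}.
#'
#' @param fit target-cell-type \code{InteractionFit}.
#' @param controlFits list of \code{InteractionFit}s for control cell types
#'   on the same organ contrast.
#' @param lfcThreshold control logFC magnitude that triggers removal (0.5).
#' @param fdrThreshold control FDR required to trust the control signal (0.1).
#' @return \code{fit} with an added logical \code{technical} column; the
#'   retained genes are those with \code{technical == FALSE}.
#' @export
filterByControlTypes <- function(fit, controlFits, lfcThreshold = 0.5,
                                 fdrThreshold = 0.1) {
    if (!length(controlFits)) stop("empty control set")
    if (!is.data.frame(controlFits[[1]])) stop("controlFits must be a list")
    technical <- rep(FALSE, nrow(fit))
    for (cf in controlFits) {
        i <- match(fit$gene, cf$gene)
        sameSign <- sign(cf$logFC[i]) == sign(fit$logFC) & fit$logFC != 0
        hit <- !is.na(i) & sameSign &
            abs(cf$logFC[i]) >= lfcThreshold & cf$FDR[i] < fdrThreshold
        technical <- technical | (hit %in% TRUE)
    }
    fit$technical <- technical
    fit
}
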