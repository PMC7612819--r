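#' Pipeline configuration
#'
#' Assembles the stage parameters for [runPipeline()] with the atlas
#' defaults (k = 30, prop = 0.05, 2-pcw age bins, marker thresholds
#' logFC > 1 / FDR < 0.1% / expressed fraction <= 70%, NMF d = 10,
#' membership fraction 0.2, spot quantile 0.9, transfer k = 30). The
#' synthetic world plants a 2-fold-per-bin abundance trend plus late-stage
#' markers in one cell type, an organ-by-cell-type expression interaction,
#' repertoire biases and 10 spatial factors, so every stage has a recorded
#' truth to recover.
#'
#' @param seed master integer seed; per-stage seeds are derived from it.
#' @param skip character vector of stage names to skip (of
#'   \code{"preprocess"}, \code{"da"}, \code{"markers"}, \code{"pseudode"},
#'   \code{"repertoire"}, \code{"microenv"}, \code{"transfer"}).
#' @param outDir optional directory; when given, stage outputs are written
#'   as CSV/JSON.
#' @param nGenes,cellsPerSample synthetic dataset size knobs.
#' @return a list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(seed = 1L, skip = character(), outDir = NULL,
                           nGenes = 400L, cellsPerSample = 400) {
    structure(list(
        seed = as.integer(seed), skip = skip, outDir = outDir,
        nGenes = as.integer(nGenes), cellsPerSample = cellsPerSample,
        k = 30L, prop = 0.05, binWidth = 2,
        daFDR = 0.1, markerLFC = 1, markerFDR = 0.001, markerFrac = 0.7,
        nmfD = 10L, detectThreshold = 0.15, fracThreshold = 0.2,
        spotQuantile = 0.9, transferK = 30L,
        trendCelltype = "T_cell", markerCelltype = "NK",
        interactionOrgan = "BM", interactionCelltype = "Monocyte",
        controlCelltype = "NK"
    ), class = "PipelineConfig")
}

#' Run the full synthetic-data analysis pipeline
#'
#' Executes simulate -> preprocess -> neighborhoods -> differential
#' abundance -> marker discovery -> pseudobulk interaction DE ->
#' repertoire statistics -> spatial microenvironments -> label transfer,
#' collecting per-stage recovery metrics against the planted ground truth.
#' Identical seeds give identical reports.
#'
#' @param config a [pipelineConfig()].
#' @return a named list of stage reports (each a list of summary numbers);
#'   written as JSON to \code{outDir} when configured.
#' @export
runPipeline <- function(config = pipelineConfig()) {
    stopifnot(inherits(config, "PipelineConfig"))
    report <- list(seed = config$seed)
    stage <- function(name, expr) {
        if (name %in% config$skip) return(NULL)
        tryCatch(expr, error = function(e)
            stop("stage [", name, "] failed: ", conditionMessage(e),
                 call. = FALSE))
    }

    ## --- simulate ---------------------------------------------------------
    G <- config$nGenes
    markerGenes <- seq(G %/% 2, G %/% 2 + 19L)   # mid-index planted markers
    interactionGenes <- seq(G %/% 4, G %/% 4 + 9L)
    trends <- NULL
    cfg0 <- simConfig(seed = config$seed, nGenes = G,
                      cellsPerSample = config$cellsPerSample)
    trends <- cfg0$abundanceTrends
    trends[config$trendCelltype, ] <- log(2) / config$binWidth
    ms <- rbind(
        data.frame(gene = markerGenes, celltype = config$markerCelltype,
                   organ = NA, direction = "late", logFC = 2),
        data.frame(gene = interactionGenes,
                   celltype = config$interactionCelltype,
                   organ = config$interactionOrgan, direction = NA,
                   logFC = 1))
    cfg <- simConfig(seed = config$seed, nGenes = G,
                     cellsPerSample = config$cellsPerSample,
                     abundanceTrends = trends, markerSpec = ms)
    cells <- stage("simulate", generateCellDataset(cfg))
    gt <- S4Vectors::metadata(cells)$ground_truth
    report$simulate <- list(n_cells = ncol(cells), n_genes = nrow(cells),
                            n_samples = length(unique(colData(cells)$sample_id)))

    ## --- preprocess -------------------------------------------------------
    if (!"preprocess" %in% config$skip) {
        cells <- qcFilter(cells, minReads = 2000,
                          minGenes = min(500, G %/% 4))
        cells <- normalizeLog(cells)
        hvg <- selectHVG(cells, nTop = min(7500, G %/% 2))
        report$preprocess <- list(cells_after_qc = ncol(cells),
                                  n_hvg = length(hvg))
    } else cells <- normalizeLog(cells)

    ## --- neighborhoods + DA ----------------------------------------------
    if (!"da" %in% config$skip) {
        emb <- SingleCellExperiment::reducedDim(cells, "embedding")
        graph <- buildKNN(emb, k = config$k)
        nhoods <- makeNeighborhoods(graph, emb, prop = config$prop,
                                    seed = config$seed)
        nhCounts <- countCellsBySample(nhoods, cells)
        labels <- labelNeighborhoods(nhoods, colData(cells)$celltype_label)
        meta <- as.data.frame(colData(nhCounts))
        facs <- facsCorrectionFactor(
            meta, gt$facsProportions[meta$sample_id[meta$sort_fraction != "unsorted"]])
        SummarizedExperiment::colData(nhCounts)$facs_factor <-
            facs[meta$sample_id]
        da <- testGestationalAge(nhCounts, binWidth = config$binWidth,
                                 labels = labels)
        tgt <- !is.na(da$label) & da$label == config$trendCelltype
        flagged <- tgt & !is.na(da$spatial_fdr) &
            da$spatial_fdr < config$daFDR & da$logFC > 0
        report$da <- list(
            n_nhoods = nrow(da),
            target_nhoods = sum(tgt),
            recall_flagged = if (sum(tgt)) sum(flagged) / sum(tgt) else NA,
            median_logfc_error = stats::median(
                abs(da$logFC[tgt] - log(2)), na.rm = TRUE))

        ## --- markers ------------------------------------------------------
        if (!"markers" %in% config$skip) {
            sets <- selectDACells(da, nhoods, config$markerCelltype, "late",
                                  fdrThreshold = config$daFDR)
            if (length(sets$setA) >= 2 && length(sets$setB) >= 2) {
                de <- rankGenesWelchT(assay(cells, "lognorm"),
                                      sets$setA, sets$setB)
                mk <- filterMarkers(de, config$markerFrac,
                                    config$markerLFC, config$markerFDR)
                truth <- paste0("G", markerGenes)
                report$markers <- list(
                    n_markers = nrow(mk),
                    precision = if (nrow(mk)) mean(mk$gene %in% truth) else NA,
                    recall = mean(truth %in% mk$gene))
            } else report$markers <- list(n_markers = 0L,
                                          precision = NA, recall = 0)
        }
    }

    ## --- pseudobulk interaction DE ---------------------------------------
    if (!"pseudode" %in% config$skip) {
        pb <- aggregatePseudobulk(cells, minCells = 20)
        fit <- fitInteractionNBGLM(pb, config$interactionOrgan,
                                   config$interactionCelltype)
        ctrl <- fitInteractionNBGLM(pb, config$interactionOrgan,
                                    config$controlCelltype)
        filt <- filterByControlTypes(fit, list(ctrl))
        truth <- paste0("G", interactionGenes)
        est <- fit$logFC[fit$gene %in% truth]
        report$pseudode <- list(
            n_pseudobulks = ncol(pb),
            median_abs_error = stats::median(abs(est - 1)),
            hits_fdr10 = sum(fit$FDR < 0.1 & fit$gene %in% truth),
            retained_after_control = sum(!filt$technical[filt$gene %in% truth]))
    }

    ## --- repertoire -------------------------------------------------------
    if (!"repertoire" %in% config$skip) {
        chains <- generateRepertoire(cfg)
        usage <- segmentUsageLogit(chains, "v_call")
        jl <- chainFeatureRegression(chains, "junction_length")
        report$repertoire <- list(
            n_chains = nrow(chains),
            v1_log_or = usage$log_or[usage$segment == "IGHV1"],
            junction_shift = jl$fit$estimate[1],
            mean_mutation_B1 = mean(
                chains$mutation_frequency[chains$group == "B1"]))
    }

    ## --- spatial microenvironments ---------------------------------------
    if (!"microenv" %in% config$skip) {
        sa <- generateSpatialAbundance(cfg)
        det <- filterDetectedTypes(sa, threshold = config$detectThreshold)
        me <- factorizeNMF(det$sa, d = config$nmfD, seed = config$seed)
        me <- microenvironmentMembership(me, config$fracThreshold)
        assign <- assignSpotsToMicroenv(me, det$sa, q = config$spotQuantile)
        mt <- matchFactors(factorLoadings(me),
                           sa@groundTruth$H[, det$retained, drop = FALSE])
        report$microenv <- list(
            retained_types = length(det$retained),
            mean_matched_cosine = mean(mt$cosine),
            spots_assigned = sum(assign))
    }

    ## --- label transfer ---------------------------------------------------
    if (!"transfer" %in% config$skip) {
        emb <- SingleCellExperiment::reducedDim(cells, "embedding")
        set.seed(config$seed + 3L)
        half <- sample(ncol(cells), ncol(cells) %/% 2)
        res <- knnGaussianLabelTransfer(
            emb[-half, , drop = FALSE], emb[half, , drop = FALSE],
            colData(cells)$celltype_label[half], k = config$transferK)
        truth <- colData(cells)$celltype_label[-half]
        report$transfer <- list(
            accuracy = mean(res$predicted == truth),
            nmi = nmiScore(res$predicted, truth))
    }

    if (!is.null(config$outDir)) {
        dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
        jsonlite::write_json(report,
                             file.path(config$outDir, "report.json"),
                             auto_unbox = TRUE, digits = NA, force = TRUE)
    }
    report
}
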