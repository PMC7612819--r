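# Shared fixture builders. Everything is generated in code; sizes are kept
# small so the whole suite stays fast.

suppressPackageStartupMessages({
    library(Matrix)
    library(SingleCellExperiment)
    library(SummarizedExperiment)
})

# Minimal SingleCellExperiment with explicit counts and metadata.
makeTinySCE <- function(counts, meta = NULL, embedding = NULL) {
    counts <- Matrix::Matrix(counts, sparse = TRUE)
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("c", seq_len(ncol(counts)))
    if (is.null(rownames(counts)))
        rownames(counts) <- paste0("g", seq_len(nrow(counts)))
    if (is.null(meta))
        meta <- data.frame(cell_id = colnames(counts),
                           sample_id = "S1", donor_id = "D1", organ = "BM",
                           age_pcw = 10, sort_fraction = "unsorted",
                           celltype_label = "A")
    sce <- SingleCellExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(meta, row.names = colnames(counts)))
    if (!is.null(embedding))
        reducedDim(sce, "embedding") <- embedding
    sce
}

# NeighborhoodSet from an explicit membership matrix (rows = neighborhoods).
makeNhoodSet <- function(membership, indexCells = NULL, kth = NULL) {
    m <- as(Matrix::Matrix(membership, sparse = TRUE), "CsparseMatrix")
    if (is.null(indexCells))
        indexCells <- apply(membership, 1, function(r) which(r > 0)[1])
    if (is.null(kth)) kth <- rep(1, nrow(m))
    new("NeighborhoodSet", membership = m,
        indexCells = as.integer(indexCells), kthDistance = as.numeric(kth),
        cellIds = paste0("c", seq_len(ncol(m))), k = 2L)
}

# A DA-ready neighborhood counts object simulated at the cell level:
# nSamplesPerBin samples in each of nBins age bins, with an optional
# log-linear trend planted in one cell type. Returns the counts SE plus
# labels and truth.
simulateDAWorld <- function(seed, cellsPerSample = 400, nDonors = 6,
                            nOrgans = 2, trendType = NULL,
                            slopePerPcw = 0, k = 30, prop = 0.05,
                            nGenes = 20, sortedShare = 0.5) {
    sortSpec <- list(sortedShare = sortedShare, depletion = 0.05)
    cfg0 <- simConfig(seed = seed, nDonors = nDonors, nOrgans = nOrgans,
                      nGenes = nGenes, cellsPerSample = cellsPerSample,
                      sortSpec = sortSpec)
    tr <- cfg0$abundanceTrends
    if (!is.null(trendType)) tr[trendType, ] <- slopePerPcw
    cfg <- simConfig(seed = seed, nDonors = nDonors, nOrgans = nOrgans,
                     nGenes = nGenes, cellsPerSample = cellsPerSample,
                     abundanceTrends = tr, sortSpec = sortSpec)
    cells <- generateCellDataset(cfg)
    emb <- reducedDim(cells, "embedding")
    graph <- buildKNN(emb, k = k)
    nhoods <- makeNeighborhoods(graph, emb, prop = prop, seed = seed)
    counts <- countCellsBySample(nhoods, cells)
    labels <- labelNeighborhoods(nhoods, colData(cells)$celltype_label)
    gt <- S4Vectors::metadata(cells)$ground_truth
    meta <- as.data.frame(colData(counts))
    facs <- facsCorrectionFactor(meta, gt$facsProportions)
    colData(counts)$facs_factor <- facs[meta$sample_id]
    list(cells = cells, nhoods = nhoods, counts = counts, labels = labels,
         truth = gt)
}
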