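test_that("all three generators are byte-identical under a fixed seed", {
    cfg <- simConfig(seed = 11, nGenes = 50, cellsPerSample = 80,
                     nDonors = 3, nOrgans = 2)
    a <- generateCellDataset(cfg); b <- generateCellDataset(cfg)
    expect_identical(assay(a, "counts"), assay(b, "counts"))
    expect_identical(as.data.frame(colData(a)), as.data.frame(colData(b)))
    expect_identical(reducedDim(a, "embedding"), reducedDim(b, "embedding"))
    r1 <- generateRepertoire(cfg); r2 <- generateRepertoire(cfg)
    expect_identical(r1, r2)
    s1 <- generateSpatialAbundance(cfg); s2 <- generateSpatialAbundance(cfg)
    expect_identical(spotCoords(s1), spotCoords(s2))
    expect_identical(abundance(s1), abundance(s2))
})

test_that("null composition shows no age-bin association beyond noise", {
    ## no planted slope: pooled chi-squared of type x age-bin counts should
    ## look null on every seed
    pvals <- vapply(1:10, function(sd) {
        cfg <- simConfig(seed = sd, nGenes = 10, cellsPerSample = 250,
                         nDonors = 6, nOrgans = 1,
                         sortSpec = list(sortedShare = 0, depletion = 1))
        cells <- generateCellDataset(cfg)
        cd <- as.data.frame(colData(cells))
        bin <- floor((cd$age_pcw - min(cd$age_pcw)) / 2)
        suppressWarnings(
            stats::chisq.test(table(cd$celltype_label, bin))$p.value)
    }, 0)
    expect_gte(sum(pvals > 0.01), 10)
})

test_that("planted marker effect matches the closed-form NB mean", {
    ## Monte-Carlo empirical means against the exact per-cell expectation
    ## derived from the recorded ground truth (type profile, marker
    ## multiplier, per-cell renormalization to the target depth)
    ms <- data.frame(gene = 1:20, celltype = "Macrophage", organ = NA,
                     direction = NA, logFC = 2)
    cfg <- simConfig(seed = 5, nGenes = 200, cellsPerSample = 500,
                     nDonors = 4, nOrgans = 1, markerSpec = ms,
                     sortSpec = list(sortedShare = 0, depletion = 1))
    cells <- generateCellDataset(cfg)
    gt <- S4Vectors::metadata(cells)$ground_truth
    lab <- colData(cells)$celltype_label
    cnt <- assay(cells, "counts")
    expect_gt(sum(lab == "Macrophage"), 200)

    expectedMean <- function(type) {
        mu <- gt$typeMeans[type, ]
        if (type == "Macrophage") mu[1:20] <- mu[1:20] * exp(2)
        mu / sum(mu) * cfg$countsPerCell
    }
    empA <- Matrix::rowMeans(cnt[, lab == "Macrophage"])[1:20]
    empB <- Matrix::rowMeans(cnt[, lab != "Macrophage"])[1:20]
    thA <- expectedMean("Macrophage")[1:20]
    ## rest is a mixture over remaining types
    others <- setdiff(unique(lab), "Macrophage")
    w <- table(lab[lab != "Macrophage"])[others]
    thB <- as.numeric(vapply(others, function(t) expectedMean(t)[1:20],
                             numeric(20)) %*% as.numeric(w)) / sum(w)
    ## empirical/theoretical agreement within Monte-Carlo error
    expect_lt(median(abs(empA / thA - 1)), 0.15)
    expect_lt(median(abs(empB / thB - 1)), 0.15)
    ## and the planted effect is visible as a large mean ratio
    expect_gt(mean(empA) / mean(empB), 3)
})

test_that("generated counts match configured NB moments", {
    cfg <- simConfig(seed = 21, nGenes = 40, cellsPerSample = 2500,
                     nDonors = 1, nOrgans = 1, nCelltypes = 2,
                     dispersion = 0.5,
                     sortSpec = list(sortedShare = 0, depletion = 1))
    cells <- generateCellDataset(cfg)
    gt <- S4Vectors::metadata(cells)$ground_truth
    lab <- colData(cells)$celltype_label
    type <- names(which.max(table(lab)))
    cnt <- as.matrix(assay(cells, "counts")[, lab == type])
    mu <- gt$typeMeans[type, ]; mu <- mu / sum(mu) * cfg$countsPerCell
    ## check the best-expressed genes, where relative error is meaningful
    top <- order(mu, decreasing = TRUE)[1:5]
    empMean <- rowMeans(cnt[top, ])
    empVar <- apply(cnt[top, ], 1, var)
    thVar <- mu[top] + 0.5 * mu[top]^2
    expect_lt(max(abs(empMean / mu[top] - 1)), 0.05)
    expect_lt(max(abs(empVar / thVar - 1)), 0.25)
})

test_that("degenerate inputs are rejected", {
    expect_error(simConfig(repertoireSpec = list(
        groups = c("A", "B"), chainsPerGroup = 10,
        vSegments = "V1", dSegments = "D1", jSegments = "J1",
        usageOdds = list(A = c(V1 = -1)),
        junctionMean = c(A = 10, B = 10), junctionSd = 1,
        npMean = c(A = 1, B = 1), mutationRate = c(A = 0, B = 0),
        seqLength = 10, dQualityProb = 1)), "odds")
    expect_error(simConfig(repertoireSpec = list(
        groups = c("A", "B"), chainsPerGroup = 10,
        vSegments = "V1", dSegments = "D1", jSegments = "J1",
        usageOdds = list(), junctionMean = c(A = 10, B = 10),
        junctionSd = 1, npMean = c(A = 1, B = 1),
        mutationRate = c(A = 1.5, B = 0), seqLength = 10,
        dQualityProb = 1)), "mutation rate")
    cfg <- simConfig(cellsPerSample = 1)
    cfg$cellsPerSample <- 0
    expect_error(generateCellDataset(cfg), "zero cells")
    cfg2 <- simConfig(embeddingSpec = list(dim = 4, centerSd = 0,
                                           withinSd = 1,
                                           minSeparation = 0.1))
    expect_error(generateCellDataset(cfg2), "degenerate")
})

test_that("repertoire ground truth is planted as configured", {
    cfg <- simConfig(seed = 31)
    rs <- cfg$repertoireSpec
    rs$chainsPerGroup <- 2000L
    rs$mutationRate <- c(B1 = 0, MatureB = 0)
    cfg$repertoireSpec <- rs
    ch <- generateRepertoire(cfg)
    expect_true(all(ch$mutation_frequency == 0))

    ## planted V1 odds of 2 in B1: empirical odds ratio from usage counts
    useB1 <- mean(ch$v_call[ch$group == "B1"] == "IGHV1")
    useMB <- mean(ch$v_call[ch$group == "MatureB"] == "IGHV1")
    orHat <- (useB1 / (1 - useB1)) / (useMB / (1 - useMB))
    expect_gt(orHat, 1.5); expect_lt(orHat, 2.7)

    ## planted -2 nt junction shift
    d <- mean(ch$junction_length[ch$group == "B1"]) -
        mean(ch$junction_length[ch$group == "MatureB"])
    expect_gt(d, -2.6); expect_lt(d, -1.4)
})

test_that("spatial generator produces the planted low-rank structure", {
    cfg <- simConfig(seed = 41, spatialSpec = list(
        nFactors = 1L, gridSize = 12L, nSlides = 1L, noiseSd = 0,
        typesPerFactor = 2, bumpRadius = 2, baseline = 0))
    sa <- generateSpatialAbundance(cfg)
    s <- svd(abundance(sa))
    expect_lt(s$d[2] / s$d[1], 1e-10)  # exactly rank 1

    cfg3 <- simConfig(seed = 42, spatialSpec = list(
        nFactors = 3L, gridSize = 15L, nSlides = 1L, noiseSd = 0.02,
        typesPerFactor = 2, bumpRadius = 3, baseline = 0.01))
    sa3 <- generateSpatialAbundance(cfg3)
    A <- abundance(sa3)
    s3 <- svd(A)
    recon <- s3$u[, 1:3] %*% diag(s3$d[1:3]) %*% t(s3$v[, 1:3])
    expect_lt(sqrt(sum((A - recon)^2)) / sqrt(sum(A^2)), 0.05)
})
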