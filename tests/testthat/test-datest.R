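test_that("age binning and the consecutive-bin organ rule work as stated", {
    meta <- data.frame(sample_id = paste0("s", 1:12),
                       age_pcw = rep(c(6, 8, 10, 12, 14, 16), 2),
                       organ = rep(c("LI", "SP"), each = 6))
    b <- binGestationalAges(meta, binWidth = 2)
    expect_identical(sort(unique(b$meta$age_bin)), 1:6)
    expect_identical(b$bins[1], 6)

    ## organ present only in bins {1, 4}: excluded; bins {2,3,4}: retained
    meta2 <- data.frame(sample_id = paste0("s", 1:5),
                        age_pcw = c(6, 12, 8, 10, 12),
                        organ = c("KI", "KI", "TH", "TH", "TH"))
    b2 <- binGestationalAges(meta2, binWidth = 2)
    expect_identical(b2$excludedOrgans, "KI")
    expect_identical(b2$retainedOrgans, "TH")
    expect_error(binGestationalAges(
        data.frame(sample_id = "s", age_pcw = 6, organ = "KI"), 2),
        "consecutive")
})

test_that("spatialFDR reduces to BH at constant weights and matches the
           brute-force weighted definition", {
    ## textbook example
    expect_equal(spatialFDR(c(0.01, 0.02, 0.03), rep(1, 3)),
                 c(0.03, 0.03, 0.03))
    expect_equal(spatialFDR(0.2, 5), 0.2)  # single test: q = p

    set.seed(4)
    for (i in 1:5) {
        p <- runif(100)
        expect_lt(max(abs(spatialFDR(p, rep(2.5, 100)) -
                          p.adjust(p, "BH"))), 1e-12)
    }

    ## brute-force evaluation of the weighted-BH definition
    bruteWBH <- function(p, w) {
        o <- order(p)
        W <- sum(w)
        qs <- numeric(length(p))
        for (i in seq_along(p)) {
            vals <- vapply(seq(i, length(p)), function(j)
                p[o[j]] * W / sum(w[o[seq_len(j)]]), 0)
            qs[o[i]] <- min(1, min(vals))
        }
        qs
    }
    set.seed(11)
    for (i in 1:50) {
        n <- sample(5:40, 1)
        p <- runif(n); w <- runif(n, 0.1, 5)
        expect_equal(spatialFDR(p, 1 / w), bruteWBH(p, w),
                     tolerance = 1e-12)
    }
    expect_error(spatialFDR(c(0.1, 0.2), c(1, 0)), "positive")
})

test_that("per-neighborhood NB GLM is offset-scale-consistent and
           sign-symmetric", {
    set.seed(6)
    K <- 60; S <- 12
    bin <- rep(1:6, each = 2)
    mu <- outer(rgamma(K, 5), rep(10, S))
    y <- matrix(rnbinom(K * S, mu = mu, size = 5), K, S)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = y),
        colData = S4Vectors::DataFrame(sample_id = paste0("s", 1:S),
                                       age_bin = bin))
    f1 <- fitNhoodGLM(se, ~ age_bin, coef = "age_bin")
    ## duplicating every sample's counts leaves composition unchanged
    se2 <- se; SummarizedExperiment::assay(se2, "counts") <- y * 2L
    f2 <- fitNhoodGLM(se2, ~ age_bin, coef = "age_bin")
    expect_equal(f1$logFC, f2$logFC, tolerance = 0.02)

    ## flipping a binary contrast negates the coefficient exactly
    SummarizedExperiment::colData(se)$grp <- rep(c(1, 0), S / 2)
    SummarizedExperiment::colData(se)$grpFlip <-
        1 - SummarizedExperiment::colData(se)$grp
    fA <- fitNhoodGLM(se, ~ grp, coef = "grp")
    fB <- fitNhoodGLM(se, ~ grpFlip, coef = "grpFlip")
    expect_equal(fA$logFC, -fB$logFC, tolerance = 1e-8)
    expect_equal(fA$pval, fB$pval, tolerance = 1e-8)

    ## an all-zero covariate column changes nothing (FACS invariant)
    SummarizedExperiment::colData(se)$facs_factor <- 0
    fC <- fitNhoodGLM(se, ~ facs_factor + age_bin, coef = "age_bin")
    expect_equal(f1$logFC, fC$logFC, tolerance = 1e-12)
    expect_equal(f1$pval, fC$pval, tolerance = 1e-12)

    ## all-zero neighborhoods are reported as NA, in input order
    y3 <- y; y3[7, ] <- 0L
    se3 <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = y3),
        colData = S4Vectors::DataFrame(sample_id = paste0("s", 1:S),
                                       age_bin = bin))
    f3 <- fitNhoodGLM(se3, ~ age_bin, coef = "age_bin")
    expect_true(is.na(f3$logFC[7]))
    expect_identical(nrow(f3), as.integer(K))
})

test_that("null simulation yields roughly uniform p-values", {
    w <- simulateDAWorld(seed = 17, cellsPerSample = 400, nDonors = 6,
                         nOrgans = 2)
    da <- testGestationalAge(w$counts, labels = w$labels)
    p <- da$pval[!is.na(da$pval)]
    expect_gt(length(p), 150)
    ks <- suppressWarnings(stats::ks.test(p, "punif"))
    expect_gt(ks$p.value, 0.01)
    ## and nothing is called significant at the 10% spatial FDR
    expect_lt(mean(da$spatial_fdr < 0.1, na.rm = TRUE), 0.02)
})

test_that("organ-specificity test flags planted enrichment and rejects
           degenerate designs", {
    cfg0 <- simConfig(seed = 23, nDonors = 4, nOrgans = 5, nGenes = 10,
                      cellsPerSample = 600,
                      sortSpec = list(sortedShare = 0, depletion = 1))
    boost <- cfg0$organBoost; boost["NK", "TH"] <- log(3)
    cfg <- simConfig(seed = 23, nDonors = 4, nOrgans = 5, nGenes = 10,
                     cellsPerSample = 600, organBoost = boost,
                     sortSpec = list(sortedShare = 0, depletion = 1))
    cells <- generateCellDataset(cfg)
    emb <- reducedDim(cells, "embedding")
    ## the atlas uses k = 100 for the across-organs test: organ
    ## neighborhood counts need the larger k for power at SpatialFDR 0.01
    g <- buildKNN(emb, k = 100)
    nh <- makeNeighborhoods(g, emb, prop = 0.05, seed = 1)
    nc <- countCellsBySample(nh, cells)
    labs <- labelNeighborhoods(nh, colData(cells)$celltype_label)
    colData(nc)$facs_factor <- 0
    res <- testOrganSpecificity(nc, "TH", labels = labs)
    tgt <- res$label == "NK"
    expect_gte(mean(res$flagged[tgt]), 0.8)
    ## no planted enrichment for Monocyte: few flags
    expect_lte(mean(res$flagged[res$label == "Monocyte"]), 0.05)

    ## target organ in fewer than two samples
    sub <- nc[, colData(nc)$organ != "TH"]
    expect_error(testOrganSpecificity(sub, "TH"), "target organ")
    one <- nc[, colData(nc)$organ == "BM"]
    expect_error(testOrganSpecificity(one, "BM"), "two organs")
})
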