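test_that("cycling fractions and the logistic group test behave as stated", {
    ## counts [0,0,3,1] -> fraction 0.5
    cnt <- matrix(c(0, 0, 3, 1), 1, 4,
                  dimnames = list("MKI67", paste0("c", 1:4)))
    sce <- makeTinySCE(cnt, meta = data.frame(
        cell_id = paste0("c", 1:4), sample_id = "S1", donor_id = "D1",
        organ = "BM", age_pcw = 10, sort_fraction = "unsorted",
        celltype_label = "B1"))
    r <- cyclingFractionTest(sce, "MKI67", rep(c("B1", "MatureB"), 2),
                             minCells = 1)
    expect_equal(r$fractions$fraction, c(0.5, 0.5))

    ## strata under 10 cells are omitted from the per-organ table
    set.seed(3)
    n <- 2000
    grp <- sample(c("B1", "MatureB"), n, TRUE)
    organ <- c(sample(c("LI", "SP"), n - 9, TRUE), rep("TH", 9))
    cyc <- rbinom(n, 1, plogis(-1.5 + log(3) * (grp == "B1")))
    cnt2 <- matrix(cyc * rpois(n, 2), 1, n,
                   dimnames = list("MKI67", paste0("c", 1:n)))
    cnt2[1, cyc == 1] <- pmax(cnt2[1, cyc == 1], 1)
    sce2 <- makeTinySCE(cnt2, meta = data.frame(
        cell_id = paste0("c", 1:n), sample_id = "S1",
        donor_id = sample(paste0("D", 1:4), n, TRUE), organ = organ,
        age_pcw = 10, sort_fraction = "unsorted", celltype_label = grp))
    r2 <- cyclingFractionTest(sce2, "MKI67", grp, minCells = 10)
    expect_false("TH" %in% r2$fractions$organ[r2$fractions$n < 10])
    ## planted cycling odds 3 for B1: reference level is B1, so the
    ## MatureB coefficient is -log(3)
    orB1 <- 1 / r2$fit$or[r2$fit$term == "groupMatureB"]
    expect_gt(orB1, 2); expect_lt(orB1, 4.5)

    expect_error(cyclingFractionTest(sce2, "ABSENT", grp), "absent")
})

test_that("chain feature regressions control covariates and honor the
           D-quality gate", {
    cfg <- simConfig(seed = 7)
    ch <- generateRepertoire(cfg)
    ## planted -2 nt junction shift (B1 46 vs MatureB 48)
    jl <- chainFeatureRegression(ch, "junction_length")
    shiftB1 <- -jl$fit$estimate[jl$fit$term == "gMatureB"]
    expect_gt(shiftB1, -2.6); expect_lt(shiftB1, -1.4)

    ## NP features only use high-quality D records: corrupting the
    ## excluded records does not move the estimate
    ch2 <- ch
    ch2$np1_length[!ch2$d_quality] <- 999
    f1 <- chainFeatureRegression(ch, "np1_length")
    f2 <- chainFeatureRegression(ch2, "np1_length")
    expect_identical(f1$fit$estimate, f2$fit$estimate)

    ## null: identical groups -> CI covers 0 in >= 9/10 seeds
    covered <- 0
    for (sd in 1:10) {
        set.seed(sd)
        n <- 300
        df <- data.frame(junction_length = rnorm(n, 48, 6),
                         group = rep(c("A", "B"), n / 2),
                         donor_id = sample(paste0("D", 1:3), n, TRUE),
                         organ = sample(c("LI", "SP"), n, TRUE))
        f <- chainFeatureRegression(df, "junction_length")
        if (f$fit$ci_lo[1] < 0 && f$fit$ci_hi[1] > 0) covered <- covered + 1
    }
    expect_gte(covered, 9)

    ## regressions reduce to the two-sample estimate when donor and organ
    ## are constant
    df0 <- data.frame(junction_length = c(rnorm(50, 40, 2), rnorm(50, 45, 2)),
                      group = rep(c("A", "B"), each = 50),
                      donor_id = "D1", organ = "LI")
    f0 <- chainFeatureRegression(df0, "junction_length")
    naive <- mean(df0$junction_length[51:100]) -
        mean(df0$junction_length[1:50])
    expect_equal(f0$fit$estimate[1], naive, tolerance = 1e-8)
})

test_that("mutationFrequency equals brute-force position counting", {
    expect_identical(mutationFrequency("ACGT", "ACGT"), 0)
    g <- paste(rep("A", 100), collapse = "")
    o <- paste(c(rep("A", 98), "C", "G"), collapse = "")
    expect_identical(mutationFrequency(o, g), 0.02)
    ## gaps and Ns are excluded from numerator and denominator
    expect_identical(mutationFrequency("AC-T", "ACGT"), 0)
    expect_identical(mutationFrequency("ACNT", "AGGT"), 1 / 3)

    set.seed(5)
    alpha <- c("A", "C", "G", "T", ".")
    for (i in 1:20) {
        L <- sample(50:200, 1)
        gs <- sample(alpha, L, replace = TRUE, prob = c(rep(0.23, 4), 0.08))
        os <- gs
        mut <- runif(L) < 0.1
        os[mut] <- sample(c("A", "C", "G", "T"), sum(mut), TRUE)
        cmp <- gs %in% c("A", "C", "G", "T") & os %in% c("A", "C", "G", "T")
        oracle <- sum(os[cmp] != gs[cmp]) / sum(cmp)
        expect_identical(mutationFrequency(paste(os, collapse = ""),
                                           paste(gs, collapse = "")),
                         oracle)
    }
    expect_error(mutationFrequency("ACG", "AC"), "length")
    expect_error(mutationFrequency("...", "..."), "comparable")
})

test_that("segment usage logistic test is calibrated and falls back on
           separation", {
    ## null: uniform usage -> few BH discoveries
    false_ <- 0; total <- 0
    for (sd in 1:3) {
        set.seed(sd)
        n <- 1500
        ch <- data.frame(v_call = sample(paste0("V", 1:8), n, TRUE),
                         group = sample(c("A", "B"), n, TRUE),
                         donor_id = sample(paste0("D", 1:4), n, TRUE),
                         organ = sample(c("LI", "SP"), n, TRUE))
        u <- segmentUsageLogit(ch, "v_call")
        false_ <- false_ + sum(u$padj < 0.05); total <- total + nrow(u)
    }
    expect_lte(false_ / total, 0.05)

    ## a segment absent from one group triggers the penalized fallback
    set.seed(9)
    ch2 <- data.frame(v_call = c(rep("V1", 30), rep("V2", 170),
                                 rep("V2", 200)),
                      group = rep(c("A", "B"), each = 200),
                      donor_id = "D1", organ = "LI")
    u2 <- segmentUsageLogit(ch2, "v_call")
    row <- u2[u2$segment == "V1", ]
    expect_true(row$penalized)
    expect_true(is.finite(row$or) && row$or > 0)
})

test_that("per-segment chi-squared matches the closed form and chisq.test", {
    r0 <- segmentUsageChi2(contingency = list(s = matrix(10, 2, 2)))
    expect_equal(r0$chisq, 0); expect_equal(r0$pval, 1)

    r1 <- segmentUsageChi2(
        contingency = list(s = matrix(c(30, 10, 10, 30), 2)))
    expect_equal(r1$chisq, 20)
    expect_equal(r1$pval, 7.744216e-06, tolerance = 1e-6)

    set.seed(12)
    for (i in 1:10) {
        tab <- matrix(rpois(8, 20) + 1, 2, 4)
        mine <- segmentUsageChi2(contingency = list(x = tab))
        ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
        expect_equal(mine$chisq, unname(ref$statistic), tolerance = 1e-8)
        expect_equal(mine$pval, ref$p.value, tolerance = 1e-8)
    }
    expect_error(segmentUsageChi2(
        contingency = list(z = matrix(0, 2, 2))), "all-zero")
})

test_that("usage PCA drops small samples, normalizes per family and
           separates planted preferences", {
    set.seed(15)
    mkChains <- function(ct, donor, nV, pv) {
        n <- length(donor)
        data.frame(v_call = sample(paste0("V", 1:nV), n, TRUE, prob = pv),
                   j_call = sample(paste0("J", 1:4), n, TRUE),
                   donor_id = donor, organ = "TH", group = ct)
    }
    donors <- rep(paste0("D", 1:8), each = 60)
    chA <- mkChains("CT_A", donors, 6, c(5, 5, 1, 1, 1, 1))
    chB <- mkChains("CT_B", donors, 6, c(1, 1, 1, 1, 5, 5))
    small <- mkChains("CT_A", rep("D9", 19), 6, rep(1, 6))  # under 20 cells
    ch <- rbind(chA, chB, small)
    res <- usagePCA(ch, sampleKey = c("donor_id", "group"),
                    celltype = "group", minCells = 20)
    expect_false(any(grepl("D9", rownames(res$scores))))
    ## proportions sum to 1 within each segment family
    v <- res$proportions[, grepl("^v_call", colnames(res$proportions))]
    j <- res$proportions[, grepl("^j_call", colnames(res$proportions))]
    expect_equal(unname(rowSums(v)), rep(1, nrow(v)), tolerance = 1e-9)
    expect_equal(unname(rowSums(j)), rep(1, nrow(j)), tolerance = 1e-9)
    ## planted disjoint V preferences separate along PC1
    sc <- res$scores
    sep <- abs(mean(sc$PC1[sc$celltype == "CT_A"]) -
               mean(sc$PC1[sc$celltype == "CT_B"]))
    sdw <- max(sd(sc$PC1[sc$celltype == "CT_A"]),
               sd(sc$PC1[sc$celltype == "CT_B"]))
    expect_gt(sep, 3 * sdw)
    ## 80% ellipse radius is the chi-squared(2) quantile
    expect_equal(res$ellipses[[1]]$radius2, qchisq(0.8, 2))
    expect_error(usagePCA(ch[1:30, ], sampleKey = "donor_id",
                          celltype = "group"), "3 samples")
})
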