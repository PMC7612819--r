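#' Cycling-cell fractions and logistic group test
#'
#' A cell is called cycling when its raw count for the proliferation marker
#' (MKI67 in the atlas) is nonzero. Per-(group, organ) fractions are
#' reported only where the stratum holds at least \code{minCells} cells; the
#' group effect is tested by logistic regression of cycling status on group,
#' controlling for donor and organ, with a Wald p-value on the group odds
#' ratio.
#'
#' @param cells \code{SingleCellExperiment} with raw counts.
#' @param gene marker gene name (row of the counts assay).
#' @param group per-cell group factor (e.g. B1 vs mature B), first level is
#'   the reference.
#' @param minCells minimum stratum size for the per-organ table (default 10).
#' @return list: \code{fractions} data.frame (group, organ, n, fraction,
#'   restricted to strata with >= minCells), \code{fit} with the group log
#'   odds ratio, its SE, OR, and Wald p.
#' @export
cyclingFractionTest <- function(cells, gene, group, minCells = 10) {
    counts <- assay(cells, "counts")
    if (!gene %in% rownames(counts)) stop("marker gene absent: ", gene)
    cycling <- as.numeric(counts[gene, ] > 0)
    cd <- as.data.frame(colData(cells))
    group <- factor(group)
    df <- data.frame(cycling = cycling, group = group,
                     donor = factor(cd$donor_id), organ = factor(cd$organ))
    tab <- stats::aggregate(cycling ~ group + organ, df,
                            FUN = function(x) c(n = length(x), f = mean(x)))
    fractions <- data.frame(group = tab$group, organ = tab$organ,
                            n = tab$cycling[, "n"],
                            fraction = tab$cycling[, "f"])
    fractions <- fractions[fractions$n >= minCells, , drop = FALSE]
    form <- if (nlevels(df$donor) > 1 && nlevels(df$organ) > 1)
        cycling ~ group + donor + organ
    else if (nlevels(df$donor) > 1) cycling ~ group + donor
    else if (nlevels(df$organ) > 1) cycling ~ group + organ
    else cycling ~ group
    g <- stats::glm(form, family = stats::binomial(), data = df)
    co <- summary(g)$coefficients
    rows <- grep("^group", rownames(co), value = TRUE)
    fit <- data.frame(term = rows,
                      log_or = co[rows, "Estimate"],
                      se = co[rows, "Std. Error"],
                      or = exp(co[rows, "Estimate"]),
                      pval = co[rows, "Pr(>|z|)"], row.names = NULL)
    list(fractions = fractions, fit = fit)
}

#' Linear regression of a chain feature on group
#'
#' Compares a repertoire feature (junction length, NP-addition lengths,
#' mutation frequency) between groups with a linear model controlling for
#' donor and organ. NP-addition features are restricted to records with
#' high-quality D gene mapping. Per-group means with normal-theory 95%
#' confidence intervals are returned for plotting.
#'
#' @param chains AIRR-style chain data.frame (see [generateRepertoire()]).
#' @param feature one of \code{"np1_length"}, \code{"np2_length"},
#'   \code{"junction_length"}, \code{"mutation_frequency"}.
#' @param group column name in \code{chains} holding the group.
#' @return list: \code{fit} (group coefficient, 95% CI, p),
#'   \code{groupMeans} (per-group mean, 95% CI, n).
#' @export
chainFeatureRegression <- function(chains, feature, group = "group") {
    feats <- c("np1_length", "np2_length", "junction_length",
               "mutation_frequency")
    if (!feature %in% feats)
        stop("feature must be one of ", paste(feats, collapse = ", "))
    df <- chains
    if (feature %in% c("np1_length", "np2_length")) {
        if (is.null(df$d_quality))
            stop("NP features require the d_quality flag")
        df <- df[df$d_quality %in% TRUE, , drop = FALSE]
    }
    df$y <- df[[feature]]
    df$g <- factor(df[[group]])
    if (any(tapply(is.na(df$y), df$g, all)))
        stop("feature entirely missing in one group")
    df$donor <- factor(df$donor_id); df$organ <- factor(df$organ)
    form <- y ~ g
    if (nlevels(df$donor) > 1) form <- stats::update(form, . ~ . + donor)
    if (nlevels(df$organ) > 1) form <- stats::update(form, . ~ . + organ)
    m <- stats::lm(form, data = df)
    co <- summary(m)$coefficients
    ci <- stats::confint(m)
    rows <- grep("^g", rownames(co), value = TRUE)
    fit <- data.frame(term = rows, estimate = co[rows, "Estimate"],
                      ci_lo = ci[rows, 1], ci_hi = ci[rows, 2],
                      pval = co[rows, "Pr(>|t|)"], row.names = NULL)
    gm <- do.call(rbind, lapply(split(df$y, df$g), function(v) {
        v <- v[!is.na(v)]
        se <- stats::sd(v) / sqrt(length(v))
        data.frame(n = length(v), mean = mean(v),
                   ci_lo = mean(v) - 1.96 * se, ci_hi = mean(v) + 1.96 * se)
    }))
    gm$group <- rownames(gm); rownames(gm) <- NULL
    list(fit = fit, groupMeans = gm)
}

#' Mutation frequency from an aligned observed/germline pair
#'
#' Fraction of mismatching positions among positions where both the observed
#' and the germline IMGT-gapped alignment carry a nucleotide; gap ("." or
#' "-") and N positions are excluded from both numerator and denominator.
#'
#' @param observed,germline equal-length aligned sequences.
#' @return mismatch fraction in [0, 1].
#' @export
mutationFrequency <- function(observed, germline) {
    o <- strsplit(toupper(observed), "")[[1]]
    g <- strsplit(toupper(germline), "")[[1]]
    if (length(o) != length(g)) stop("aligned sequences differ in length")
    valid <- c("A", "C", "G", "T")
    comparable <- o %in% valid & g %in% valid
    if (!sum(comparable)) stop("no comparable positions")
    sum(o[comparable] != g[comparable]) / sum(comparable)
}

## Firth-penalized logistic regression (Jeffreys-prior score adjustment),
## used as the fallback when the usage model separates. Small and dense
## designs only.
.firthLogit <- function(X, y, maxit = 100, tol = 1e-8) {
    beta <- rep(0, ncol(X))
    for (it in seq_len(maxit)) {
        eta <- as.vector(X %*% beta)
        p <- 1 / (1 + exp(-eta))
        w <- p * (1 - p)
        XW <- X * w
        XtWX <- crossprod(X, XW)
        R <- tryCatch(chol(XtWX), error = function(e) NULL)
        if (is.null(R)) break
        ## hat diagonal of the weighted design
        Xs <- X * sqrt(w)
        h <- rowSums((Xs %*% chol2inv(R)) * Xs)
        U <- crossprod(X, y - p + h * (0.5 - p))
        step <- chol2inv(R) %*% U
        beta <- beta + as.vector(step)
        if (max(abs(step)) < tol) break
    }
    eta <- as.vector(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    XtWX <- crossprod(X, X * p * (1 - p))
    se <- sqrt(diag(solve(XtWX)))
    list(coefficients = stats::setNames(beta, colnames(X)), se = se)
}

#' Per-segment usage test by logistic regression
#'
#' For every gene segment of a class (e.g. all V segments observed), usage
#' is coded used/not-used per chain and regressed on group with donor and
#' organ as fixed-effect controls. Odds ratios get Wald p-values,
#' BH-adjusted across the segments of the class. Segments with fewer than
#' \code{minUses} total uses are skipped. On (quasi-)separation the fit
#' falls back to Firth-penalized logistic regression and is flagged.
#'
#' @param chains AIRR-style chain data.frame.
#' @param segmentClass column holding the segment call (\code{"v_call"},
#'   \code{"j_call"}, ...).
#' @param group grouping column name (first factor level = reference).
#' @param minUses minimum total uses for a segment to be tested (default 5).
#' @return data.frame: segment, log_or, or, se, pval, padj, penalized.
#' @export
segmentUsageLogit <- function(chains, segmentClass = "v_call",
                              group = "group", minUses = 5) {
    seg <- chains[[segmentClass]]
    g <- factor(chains[[group]])
    donor <- factor(chains$donor_id); organ <- factor(chains$organ)
    segs <- names(which(table(seg) >= minUses))
    if (!length(segs)) stop("no segment reaches minUses")
    out <- lapply(segs, function(s) {
        df <- data.frame(used = as.numeric(seg == s), g = g,
                         donor = donor, organ = organ)
        form <- used ~ g
        if (nlevels(donor) > 1) form <- stats::update(form, . ~ . + donor)
        if (nlevels(organ) > 1) form <- stats::update(form, . ~ . + organ)
        sep <- any(tapply(df$used, df$g, function(u)
            all(u == 0) || all(u == 1)))
        fitGlm <- suppressWarnings(
            stats::glm(form, family = stats::binomial(), data = df))
        big <- any(abs(stats::coef(fitGlm)[-1]) > 15, na.rm = TRUE)
        coefName <- grep("^g", names(stats::coef(fitGlm)), value = TRUE)[1]
        if (sep || big || !fitGlm$converged || anyNA(stats::coef(fitGlm))) {
            X <- .daModelMatrix(form[-2], df)
            f <- .firthLogit(X, df$used)
            est <- f$coefficients[coefName]; se <- f$se[match(coefName, colnames(X))]
            pen <- TRUE
        } else {
            co <- summary(fitGlm)$coefficients
            est <- co[coefName, "Estimate"]; se <- co[coefName, "Std. Error"]
            pen <- FALSE
        }
        z <- est / se
        data.frame(segment = s, log_or = est, or = exp(est), se = se,
                   pval = 2 * stats::pnorm(-abs(z)), penalized = pen,
                   row.names = NULL)
    })
    res <- do.call(rbind, out)
    res$padj <- stats::p.adjust(res$pval, "BH")
    res
}

#' Per-segment usage test by Pearson chi-squared
#'
#' For each segment, the used/not-used x cell-type contingency table is
#' tested with Pearson's chi-squared statistic (no continuity correction),
#' BH-adjusted across segments.
#'
#' @param chains AIRR-style chain data.frame, or \code{NULL} when
#'   \code{contingency} is given.
#' @param segmentClass,celltype column names in \code{chains}.
#' @param contingency alternatively, a named list of 2 x K used/not-used
#'   tables, one per segment.
#' @return data.frame: segment, chisq, df, pval, padj.
#' @export
segmentUsageChi2 <- function(chains = NULL, segmentClass = "v_call",
                             celltype = "group", contingency = NULL) {
    if (is.null(contingency)) {
        seg <- chains[[segmentClass]]
        ct <- factor(chains[[celltype]])
        contingency <- lapply(unique(seg), function(s)
            rbind(used = table(ct[seg == s]),
                  not = table(ct[seg != s])))
        names(contingency) <- unique(seg)
    }
    out <- lapply(names(contingency), function(s) {
        tab <- as.matrix(contingency[[s]])
        if (all(tab == 0)) stop("all-zero contingency table for ", s)
        n <- sum(tab)
        E <- outer(rowSums(tab), colSums(tab)) / n
        use <- E > 0
        chisq <- sum((tab[use] - E[use])^2 / E[use])
        df <- (nrow(tab) - 1) * (ncol(tab) - 1)
        data.frame(segment = s, chisq = chisq, df = df,
                   pval = stats::pchisq(chisq, df, lower.tail = FALSE),
                   row.names = NULL)
    })
    res <- do.call(rbind, out)
    res$padj <- stats::p.adjust(res$pval, "BH")
    res
}

#' PCA of per-sample segment-usage proportions
#'
#' Each sample's chains are converted into usage proportion vectors within
#' each segment family (e.g. TRAV, TRAJ, TRBV, TRBJ - proportions sum to 1
#' per family per sample), samples with fewer than \code{minCells} cells are
#' dropped, and a PCA is run on the centered proportions. Per-cell-type
#' centroids and 80% normal confidence ellipses (chi-squared(2) quantile
#' 3.219 on the 2-D score covariance) are returned for plotting.
#'
#' @param chains AIRR-style chain data.frame with segment-call columns.
#' @param sampleKey column(s) defining a sample (e.g.
#'   \code{c("donor_id", "organ", "group")}).
#' @param celltype column giving the cell type of each chain (used for
#'   centroids); must be constant within a sample.
#' @param segmentClasses segment-call columns to use.
#' @param minCells minimum chains per sample (default 20).
#' @return list: \code{scores} (sample x PC data.frame with cell type and n),
#'   \code{proportions} (the usage matrix), \code{centroids},
#'   \code{ellipses} (per cell type: centroid, 2x2 covariance, radius2 =
#'   qchisq(0.8, 2)), \code{pca} (the prcomp object).
#' @export
usagePCA <- function(chains, sampleKey = c("donor_id", "organ", "group"),
                     celltype = "group",
                     segmentClasses = c("v_call", "j_call"),
                     minCells = 20) {
    key <- do.call(paste, c(chains[sampleKey], sep = "|"))
    keep <- names(which(table(key) >= minCells))
    if (length(keep) < 3) stop("fewer than 3 samples retained")
    sub <- chains[key %in% keep, , drop = FALSE]
    key <- key[key %in% keep]
    blocks <- lapply(segmentClasses, function(sc) {
        tab <- table(key, sub[[sc]])
        prop <- tab / rowSums(tab)
        m <- matrix(as.numeric(prop), nrow(tab), ncol(tab),
                    dimnames = dimnames(tab))
        colnames(m) <- paste(sc, colnames(m), sep = ":")
        m
    })
    P <- do.call(cbind, blocks)
    pca <- stats::prcomp(P, center = TRUE, scale. = FALSE)
    nc <- min(5, ncol(pca$x))
    sc <- as.data.frame(pca$x[, seq_len(nc), drop = FALSE])
    ctPerSample <- tapply(as.character(sub[[celltype]]), key,
                          function(v) v[1])
    sc$celltype <- as.character(ctPerSample[rownames(P)])
    sc$n <- as.integer(table(key)[rownames(P)])
    cent <- do.call(rbind, lapply(split(sc[, 1:2], sc$celltype), colMeans))
    ell <- lapply(split(sc[, 1:2], sc$celltype), function(d) {
        list(center = colMeans(d),
             cov = if (nrow(d) > 1) stats::cov(d) else diag(2) * 0,
             radius2 = stats::qchisq(0.8, 2))
    })
    list(scores = sc, proportions = P, centroids = cent,
         ellipses = ell, pca = pca)
}
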