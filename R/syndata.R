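#' Simulation configuration for synthetic atlas data
#'
#' Builds the configuration object consumed by [generateCellDataset()],
#' [generateRepertoire()] and [generateSpatialAbundance()]. Defaults emulate
#' the statistical structure of a multi-donor, multi-organ prenatal immune
#' atlas: samples spanning 7-17 post-conception weeks (pcw) across several
#' organs, cell-type composition drifting log-linearly with age, CD45-sorted
#' libraries enriched for immune cells, droplet-style negative-binomial gene
#' counts with planted markers, paired-chain repertoires with group-biased
#' segment usage and low fetal mutation loads, and spatial abundances built
#' from compact low-rank microenvironment factors plus noise.
#'
#' @param seed integer; fixes all randomness (byte-identical output).
#' @param nDonors,nOrgans,nCelltypes,nGenes dataset dimensions.
#' @param ageRange numeric length-2, gestational age interval in pcw.
#' @param cellsPerSample expected cells per sample (Poisson mean).
#' @param countsPerCell expected total raw counts per cell.
#' @param dispersion shared NB dispersion of gene counts (var = mu + disp*mu^2).
#' @param abundanceTrends nCelltypes x nOrgans matrix of log-linear age slopes
#'   (natural log change in relative abundance per pcw); 0 = no age effect.
#' @param organBoost nCelltypes x nOrgans matrix of natural-log boosts to the
#'   baseline composition, planting organ-specific enrichment; 0 = none.
#' @param markerSpec data.frame with columns \code{gene} (index into genes),
#'   \code{celltype}, \code{organ} (NA = all), \code{direction} ("late",
#'   "early" or NA = constitutive), \code{logFC} (natural log). Planted by
#'   multiplying the NB mean for cells matching the condition.
#' @param sortSpec list: \code{sortedShare} (fraction of dissociations that
#'   are CD45-FACS sorted), \code{depletion} (retention factor of the
#'   off-gate cells in a sorted library).
#' @param embeddingSpec list: \code{dim}, \code{centerSd} (spread of cell-type
#'   centers), \code{withinSd} (within-type spread), \code{minSeparation}.
#' @param repertoireSpec list describing chain generation: \code{groups},
#'   \code{chainsPerGroup}, \code{vSegments}/\code{dSegments}/\code{jSegments},
#'   \code{usageOdds} (named list group -> named odds multipliers on V
#'   segments), \code{junctionMean}/\code{junctionSd} per group (nt),
#'   \code{npMean} per group (nt, Poisson), \code{mutationRate} per group,
#'   \code{seqLength}, \code{dQualityProb}.
#' @param spatialSpec list: \code{nFactors}, \code{gridSize}, \code{nSlides},
#'   \code{noiseSd} (as a fraction of the mean signal), \code{typesPerFactor},
#'   \code{bumpRadius}, \code{baseline}.
#' @param lateBreak pcw threshold splitting "early" from "late" cells for
#'   stage-specific planted markers (default midpoint of \code{ageRange}).
#'
#' @return a list of class \code{SimConfig}.
#' @export
simConfig <- function(seed = 1L,
                      nDonors = 6L, nOrgans = 4L, nCelltypes = 6L,
                      nGenes = 200L,
                      ageRange = c(7, 17),
                      cellsPerSample = 400,
                      countsPerCell = 5000,
                      dispersion = 0.4,
                      abundanceTrends = NULL,
                      organBoost = NULL,
                      markerSpec = NULL,
                      sortSpec = list(sortedShare = 0.5, depletion = 0.05),
                      embeddingSpec = list(dim = 10L, centerSd = 5,
                                           withinSd = 1, minSeparation = 1e-6),
                      repertoireSpec = NULL,
                      spatialSpec = NULL,
                      lateBreak = NULL) {
    organs <- c("BM", "LI", "SP", "TH", "SK", "GU", "KI", "YS")
    typePool <- c("Macrophage", "Monocyte", "NK", "B_cell", "T_cell",
                  "Stroma", "DC", "ILC", "Mast_cell", "Progenitor")
    immunePool <- c(TRUE, TRUE, TRUE, TRUE, TRUE,
                    FALSE, TRUE, TRUE, TRUE, TRUE)
    if (nOrgans > length(organs)) organs <- c(organs, paste0("OR", seq_len(nOrgans)))
    if (nCelltypes > length(typePool)) {
        extra <- paste0("CT", seq_len(nCelltypes))
        typePool <- c(typePool, extra); immunePool <- c(immunePool, rep(TRUE, nCelltypes))
    }
    celltypes <- typePool[seq_len(nCelltypes)]
    immune <- immunePool[seq_len(nCelltypes)]
    if (is.null(abundanceTrends))
        abundanceTrends <- matrix(0, nCelltypes, nOrgans,
                                  dimnames = list(celltypes, organs[seq_len(nOrgans)]))
    if (is.null(organBoost))
        organBoost <- matrix(0, nCelltypes, nOrgans,
                             dimnames = dimnames(abundanceTrends))
    if (is.null(markerSpec))
        markerSpec <- data.frame(gene = integer(), celltype = character(),
                                 organ = character(), direction = character(),
                                 logFC = numeric(), stringsAsFactors = FALSE)
    if (is.null(repertoireSpec))
        repertoireSpec <- list(
            groups = c("B1", "MatureB"),
            chainsPerGroup = 1000L,
            vSegments = paste0("IGHV", 1:8),
            dSegments = paste0("IGHD", 1:4),
            jSegments = paste0("IGHJ", 1:4),
            usageOdds = list(B1 = c(IGHV1 = 2)),
            junctionMean = c(B1 = 46, MatureB = 48),
            junctionSd = 6,
            npMean = c(B1 = 2, MatureB = 5),
            mutationRate = c(B1 = 0.005, MatureB = 0.02),
            seqLength = 300L,
            dQualityProb = 0.3,
            withSequences = TRUE
        )
    if (is.null(spatialSpec))
        spatialSpec <- list(nFactors = 10L, gridSize = 30L, nSlides = 2L,
                            noiseSd = 0.1, typesPerFactor = 2:3,
                            bumpRadius = NULL, baseline = 0.02)
    if (is.null(lateBreak)) lateBreak <- mean(ageRange)
    stopifnot(nCelltypes >= 2L, nDonors >= 1L, nOrgans >= 1L,
              ageRange[2] > ageRange[1], cellsPerSample > 0,
              all(dim(abundanceTrends) == c(nCelltypes, nOrgans)))
    if (any(unlist(repertoireSpec$usageOdds) <= 0))
        stop("usage odds must be positive")
    mr <- repertoireSpec$mutationRate
    if (any(mr < 0 | mr > 1)) stop("mutation rate must lie in [0, 1]")
    cfg <- list(seed = as.integer(seed), nDonors = as.integer(nDonors),
                nOrgans = as.integer(nOrgans), nCelltypes = as.integer(nCelltypes),
                nGenes = as.integer(nGenes), ageRange = ageRange,
                cellsPerSample = cellsPerSample, countsPerCell = countsPerCell,
                dispersion = dispersion, abundanceTrends = abundanceTrends,
                organBoost = organBoost,
                markerSpec = markerSpec, sortSpec = sortSpec,
                embeddingSpec = embeddingSpec, repertoireSpec = repertoireSpec,
                spatialSpec = spatialSpec, lateBreak = lateBreak,
                organs = organs[seq_len(nOrgans)], celltypes = celltypes,
                immune = stats::setNames(immune, celltypes))
    class(cfg) <- "SimConfig"
    cfg
}

#' Generate a synthetic multi-donor multi-organ cell dataset
#'
#' Draws one sample per (donor, organ) pair (plus a CD45-sorted companion
#' library for sorted dissociations), assigns each donor a gestational age,
#' composes samples according to the configured log-linear abundance trends,
#' places cells in a latent embedding via per-type Gaussians, and draws gene
#' counts from a negative binomial with planted marker effects. CD45-sorted
#' libraries are thinned on the off-gate cells and the true sorting fractions
#' recorded, so FACS-correction recovery is testable downstream.
#'
#' @param config a [simConfig()] object.
#' @return a \linkS4class{SingleCellExperiment} with assay \code{"counts"},
#'   per-cell metadata in \code{colData} (donor_id, organ, age_pcw,
#'   sort_fraction, celltype_label, sample_id), the latent embedding in
#'   \code{reducedDim(x, "embedding")}, and the full planted ground truth in
#'   \code{metadata(x)$ground_truth}.
#' @export
#' @importFrom SingleCellExperiment SingleCellExperiment reducedDim<- reducedDim
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom stats rnorm rpois rnbinom rbinom runif rmultinom setNames
generateCellDataset <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    if (config$cellsPerSample <= 0) stop("zero cells requested")
    set.seed(config$seed)
    K <- config$nCelltypes; G <- config$nGenes
    types <- config$celltypes; organs <- config$organs

    ## latent embedding centers, rejected if degenerate
    es <- config$embeddingSpec
    centers <- matrix(rnorm(K * es$dim, sd = es$centerSd), K, es$dim,
                      dimnames = list(types, NULL))
    dd <- as.matrix(stats::dist(centers))
    if (min(dd[upper.tri(dd)]) < es$minSeparation)
        stop("degenerate (near-identical) cell-type centers")

    ## baseline gene means per type: shared lognormal profile, type-specific
    ## tilts so types are distinguishable in expression space
    ## heavy-tailed profile: a few genes soak up most counts so per-gene
    ## detection fractions look like droplet data rather than dense arrays
    base <- exp(rnorm(G, 0, 2)); base <- base / sum(base)
    ## planted markers sit at low baseline expression (20th percentile):
    ## detectable when induced, not ubiquitous - like real markers
    if (nrow(config$markerSpec))
        base[config$markerSpec$gene] <- stats::quantile(base, 0.2)
    typeMu <- matrix(rep(base, K), K, G, byrow = TRUE,
                     dimnames = list(types, paste0("G", seq_len(G))))
    tilt <- matrix(exp(rnorm(K * G, 0, 0.1)), K, G)
    typeMu <- typeMu * tilt

    ## donor ages spread over the range
    ages <- round(seq(config$ageRange[1], config$ageRange[2],
                      length.out = config$nDonors), 1)

    ## stage-specific expression programs move cells in latent space: types
    ## carrying direction-tagged markers get a late-stage embedding shift,
    ## so early- and late-specific neighborhoods can form
    ms0 <- config$markerSpec
    stageTypes <- unique(ms0$celltype[!is.na(ms0$direction)])
    stageShift <- matrix(0, K, es$dim, dimnames = list(types, NULL))
    shiftMag <- if (is.null(es$stageShift)) 3 else es$stageShift
    for (tp in intersect(stageTypes, types)) {
        v <- rnorm(es$dim)
        stageShift[tp, ] <- shiftMag * v / sqrt(sum(v^2))
    }

    ## baseline composition: one Dirichlet-like draw shared by all organs,
    ## so organ differences exist exactly where organBoost plants them
    typeW <- stats::rgamma(K, shape = 4)
    baseComp <- matrix(typeW, K, config$nOrgans,
                       dimnames = list(types, organs))
    baseComp <- baseComp * exp(config$organBoost)
    baseComp <- sweep(baseComp, 2, colSums(baseComp), "/")

    midAge <- mean(config$ageRange)
    sortedDonor <- runif(config$nDonors) < config$sortSpec$sortedShare

    cells <- list(); emb <- list(); cnts <- list()
    sampleFacs <- list()
    cellCounter <- 0L
    for (d in seq_len(config$nDonors)) {
        for (o in seq_len(config$nOrgans)) {
            age <- ages[d]
            p <- baseComp[, o] * exp(config$abundanceTrends[, o] * (age - midAge))
            p <- p / sum(p)
            n <- rpois(1, config$cellsPerSample)
            if (n == 0) next
            lab <- sample(types, n, replace = TRUE, prob = p)
            fracs <- "unsorted"
            keep <- list(unsorted = rep(TRUE, n))
            if (sortedDonor[d]) {
                ## CD45+ sorted companion library from the same dissociation:
                ## off-gate (non-immune) cells retained at the depletion rate
                fracs <- c("unsorted", "CD45pos")
                isImm <- config$immune[lab]
                keep$CD45pos <- isImm | (runif(n) < config$sortSpec$depletion)
                ## true live-cell share of the CD45+ gate in this dissociation
                piPos <- mean(isImm)
                sampleFacs[[paste0("D", d, "_", organs[o], "_CD45pos")]] <- piPos
            }
            for (fr in fracs) {
                sel <- which(keep[[fr]])
                if (!length(sel)) next
                m <- length(sel)
                sid <- paste0("D", d, "_", organs[o], "_", fr)
                ids <- paste0("cell", cellCounter + seq_len(m))
                cellCounter <- cellCounter + m
                cells[[sid]] <- data.frame(
                    cell_id = ids, donor_id = paste0("D", d),
                    organ = organs[o], age_pcw = age, sort_fraction = fr,
                    celltype_label = lab[sel], sample_id = sid,
                    stringsAsFactors = FALSE)
                shift <- if (age >= config$lateBreak)
                    stageShift[lab[sel], , drop = FALSE] else 0
                emb[[sid]] <- centers[lab[sel], , drop = FALSE] + shift +
                    matrix(rnorm(m * es$dim, sd = es$withinSd), m, es$dim)
            }
        }
    }
    obs <- do.call(rbind, cells); rownames(obs) <- obs$cell_id
    E <- do.call(rbind, emb); rownames(E) <- obs$cell_id
    n <- nrow(obs)

    ## per-cell NB means: type profile scaled to target depth, marker effects
    mu <- typeMu[obs$celltype_label, , drop = FALSE]
    ms <- config$markerSpec
    if (nrow(ms)) {
        late <- obs$age_pcw >= config$lateBreak
        for (i in seq_len(nrow(ms))) {
            hit <- obs$celltype_label == ms$celltype[i]
            if (!is.na(ms$organ[i])) hit <- hit & obs$organ == ms$organ[i]
            if (!is.na(ms$direction[i]))
                hit <- hit & (if (ms$direction[i] == "late") late else !late)
            mu[hit, ms$gene[i]] <- mu[hit, ms$gene[i]] * exp(ms$logFC[i])
        }
    }
    mu <- mu / rowSums(mu) * config$countsPerCell
    counts <- matrix(rnbinom(n * G, mu = mu, size = 1 / config$dispersion),
                     n, G)
    dimnames(counts) <- list(obs$cell_id, colnames(typeMu))
    counts <- Matrix::Matrix(t(counts), sparse = TRUE)  # genes x cells

    sce <- SingleCellExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(obs, row.names = obs$cell_id))
    SingleCellExperiment::reducedDim(sce, "embedding") <- E
    S4Vectors::metadata(sce)$ground_truth <- list(
        trends = config$abundanceTrends, organBoost = config$organBoost,
        markers = config$markerSpec,
        centers = centers, typeMeans = typeMu, immune = config$immune,
        lateBreak = config$lateBreak, donorAges = setNames(ages, paste0("D", seq_len(config$nDonors))),
        facsProportions = unlist(sampleFacs), depletion = config$sortSpec$depletion,
        dispersion = config$dispersion)
    sce
}

#' Generate a synthetic immune-receptor repertoire
#'
#' Produces an AIRR-Rearrangement-style table of heavy-chain records for the
#' configured cell groups, with group-biased V segment usage (planted odds),
#' group-shifted junction lengths, Poisson NP-addition lengths, and per-chain
#' germline/observed alignment pairs mutated at the planted rate.
#'
#' @param config a [simConfig()] object; uses \code{config$repertoireSpec}.
#' @return a \code{data.frame} with AIRR columns (cell_id, locus, v_call,
#'   d_call, j_call, junction_length, np1_length, np2_length, productive,
#'   sequence_alignment, germline_alignment, mutation_frequency, d_quality)
#'   plus group/donor/organ covariates; the planted parameters are attached
#'   as \code{attr(x, "ground_truth")}.
#' @export
generateRepertoire <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    rs <- config$repertoireSpec
    if (length(rs$groups) < 2L) stop("repertoireSpec must define >= 2 groups")
    if (any(unlist(rs$usageOdds) <= 0)) stop("usage odds must be positive")
    if (any(rs$mutationRate < 0 | rs$mutationRate > 1))
        stop("mutation rate must lie in [0, 1]")
    set.seed(config$seed + 1L)
    nV <- length(rs$vSegments)
    baseP <- rev(seq_len(nV)); baseP <- baseP / sum(baseP)  # skewed baseline
    alphabet <- c("A", "C", "G", "T")
    out <- list()
    for (g in rs$groups) {
        m <- rs$chainsPerGroup
        p <- baseP
        odds <- rs$usageOdds[[g]]
        if (!is.null(odds)) {
            i <- match(names(odds), rs$vSegments)
            p[i] <- p[i] * odds
            p <- p / sum(p)
        }
        jl <- pmax(0L, round(rnorm(m, rs$junctionMean[[g]], rs$junctionSd)))
        np1 <- rpois(m, rs$npMean[[g]]); np2 <- rpois(m, rs$npMean[[g]])
        L <- rs$seqLength
        rate <- rs$mutationRate[[g]]
        withSeq <- is.null(rs$withSequences) || isTRUE(rs$withSequences)
        if (withSeq) {
            germ <- vapply(seq_len(m), function(i)
                paste(sample(alphabet, L, replace = TRUE), collapse = ""), "")
            obsSeq <- vapply(seq_len(m), function(i) {
                s <- strsplit(germ[i], "")[[1]]
                nm <- rbinom(1, L, rate)
                if (nm > 0) {
                    pos <- sample.int(L, nm)
                    s[pos] <- vapply(s[pos], function(b)
                        sample(setdiff(alphabet, b), 1), "")
                }
                paste(s, collapse = "")
            }, "")
        } else {
            germ <- NA_character_; obsSeq <- NA_character_
        }
        out[[g]] <- data.frame(
            cell_id = paste0(g, "_cell", seq_len(m)),
            locus = "IGH",
            v_call = sample(rs$vSegments, m, replace = TRUE, prob = p),
            d_call = sample(rs$dSegments, m, replace = TRUE),
            j_call = sample(rs$jSegments, m, replace = TRUE),
            junction_length = jl, np1_length = np1, np2_length = np2,
            productive = TRUE,
            sequence_alignment = obsSeq, germline_alignment = germ,
            d_quality = runif(m) < rs$dQualityProb,
            group = g,
            donor_id = sample(paste0("D", seq_len(config$nDonors)), m, TRUE),
            organ = sample(config$organs, m, TRUE),
            stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out); rownames(res) <- NULL
    ## mutation frequency is defined only when an alignment pair exists
    res$mutation_frequency <- NA_real_
    hasSeq <- !is.na(res$sequence_alignment)
    res$mutation_frequency[hasSeq] <- vapply(which(hasSeq), function(i)
        mutationFrequency(res$sequence_alignment[i],
                          res$germline_alignment[i]), 0)
    attr(res, "ground_truth") <- list(
        usageOdds = rs$usageOdds, junctionMean = rs$junctionMean,
        npMean = rs$npMean, mutationRate = rs$mutationRate,
        baselineVProb = setNames(baseP, rs$vSegments))
    res
}

#' Generate a synthetic spot x cell-type spatial abundance matrix
#'
#' Builds, per slide, spatially compact factors (Gaussian bumps on a square
#' grid of spots) with nonnegative cell-type loadings, and returns
#' abundance = W H + nonnegative noise. The planted W, H and per-factor spot
#' regions are recorded as ground truth for recovery tests.
#'
#' @param config a [simConfig()] object; uses \code{config$spatialSpec}.
#' @return a \linkS4class{SpatialAbundance}; \code{groundTruth} carries
#'   \code{W}, \code{H}, \code{memberTypes} (planted cell types per factor)
#'   and \code{region} (logical spots x factors matrix of bump support).
#' @export
generateSpatialAbundance <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    ss <- config$spatialSpec
    if (ss$nFactors <= 0) stop("need at least one factor")
    set.seed(config$seed + 2L)
    ## spatial deconvolution resolves finer types than the coarse scRNA
    ## labels; make sure the vocabulary exceeds the factor count
    types <- config$celltypes
    d <- ss$nFactors
    if (length(types) < d + 5L)
        types <- c(types, paste0("CT", seq_len(d + 5L - length(types))))
    K <- length(types)
    g <- ss$gridSize
    r <- if (is.null(ss$bumpRadius)) g / 6 else ss$bumpRadius

    ## loadings: every microenvironment is hallmarked by one anchor cell
    ## type of its own plus shared types rotated round-robin through the
    ## remaining vocabulary, mirroring how tissue zones combine a defining
    ## population with types found across several zones
    if (K <= d) stop("need more cell types than factors")
    H <- matrix(0, d, K, dimnames = list(paste0("F", seq_len(d)), types))
    memberTypes <- vector("list", d)
    spare <- types[(d + 1):K]
    nShare <- max(1L, min(ss$typesPerFactor) - 1L)
    for (f in seq_len(d)) {
        anchor <- types[f]
        shared <- spare[((f - 1L + seq_len(nShare) - 1L) %% length(spare)) + 1L]
        H[f, anchor] <- runif(1, 0.7, 1)
        H[f, shared] <- runif(length(shared), 0.4, 0.6)
        memberTypes[[f]] <- sort(c(anchor, shared))
    }
    if (any(H < 0)) stop("negative loadings")

    ## zone centers on a jittered lattice so compact regions tile the slide
    grid <- expand.grid(x = seq_len(g), y = seq_len(g))
    nSide <- ceiling(sqrt(d))
    pitch <- (g - 2 * r) / nSide
    lattice <- expand.grid(i = seq_len(nSide), j = seq_len(nSide))
    W <- NULL; coords <- NULL; slide <- NULL
    for (s in seq_len(ss$nSlides)) {
        slots <- lattice[sample.int(nrow(lattice), d), , drop = FALSE]
        cx <- 1 + r + (slots$i - 0.5) * pitch + runif(d, -r / 2, r / 2)
        cy <- 1 + r + (slots$j - 0.5) * pitch + runif(d, -r / 2, r / 2)
        Ws <- vapply(seq_len(d), function(f)
            exp(-((grid$x - cx[f])^2 + (grid$y - cy[f])^2) / (2 * r^2)),
            numeric(nrow(grid)))
        W <- rbind(W, Ws)
        coords <- rbind(coords, as.matrix(grid))
        slide <- c(slide, rep(paste0("slide", s), nrow(grid)))
    }
    colnames(W) <- rownames(H)
    signal <- W %*% H + ss$baseline
    noise <- matrix(abs(rnorm(length(signal),
                              sd = ss$noiseSd * mean(signal))),
                    nrow(signal), ncol(signal))
    A <- signal + noise
    rownames(A) <- paste0("spot", seq_len(nrow(A)))
    region <- W > 0.1 * matrix(apply(W, 2, max), nrow(W), d, byrow = TRUE)
    SpatialAbundance(A, coords, slide,
                     groundTruth = list(W = W, H = H,
                                        memberTypes = memberTypes,
                                        region = region))
}
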