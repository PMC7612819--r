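#' Filter cell types below the spatial detection threshold
#'
#' A cell type is excluded from microenvironment analysis when its
#' \code{q}-quantile abundance is below the detection threshold in every
#' slide (the atlas rule: 99% quantile below 0.15 in all slides of an
#' organ). A type clearing the threshold on any one slide is retained.
#'
#' @param sa a \linkS4class{SpatialAbundance}.
#' @param q quantile per (type, slide) (default 0.99).
#' @param threshold detection threshold (default 0.15).
#' @return list: \code{sa} restricted to retained types, \code{retained},
#'   \code{excluded}.
#' @export
filterDetectedTypes <- function(sa, q = 0.99, threshold = 0.15) {
    stopifnot(q > 0, q < 1)
    A <- abundance(sa)
    slides <- unique(slideId(sa))
    qs <- sapply(slides, function(s)
        apply(A[slideId(sa) == s, , drop = FALSE], 2,
              stats::quantile, probs = q, names = FALSE))
    qs <- matrix(qs, ncol(A), length(slides),
                 dimnames = list(colnames(A), slides))
    detected <- apply(qs, 1, function(v) any(v >= threshold))
    if (!any(detected)) stop("all cell types below the detection threshold")
    out <- SpatialAbundance(A[, detected, drop = FALSE], spotCoords(sa),
                            slideId(sa), sa@groundTruth)
    list(sa = out, retained = colnames(A)[detected],
         excluded = colnames(A)[!detected])
}

## Nonnegative double SVD initialization (the "nndsvda" variant: zeros are
## filled with the matrix mean, which keeps multiplicative updates alive and
## is deterministic).
.nndsvda <- function(A, d) {
    s <- svd(A, nu = d, nv = d)
    W <- matrix(0, nrow(A), d); H <- matrix(0, d, ncol(A))
    W[, 1] <- sqrt(s$d[1]) * abs(s$u[, 1])
    H[1, ] <- sqrt(s$d[1]) * abs(s$v[, 1])
    for (j in seq_len(d)[-1]) {
        u <- s$u[, j]; v <- s$v[, j]
        up <- pmax(u, 0); un <- pmax(-u, 0)
        vp <- pmax(v, 0); vn <- pmax(-v, 0)
        npos <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
        nneg <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
        if (npos >= nneg && npos > 0) {
            W[, j] <- sqrt(s$d[j] * npos) * up / sqrt(sum(up^2))
            H[j, ] <- sqrt(s$d[j] * npos) * vp / sqrt(sum(vp^2))
        } else if (nneg > 0) {
            W[, j] <- sqrt(s$d[j] * nneg) * un / sqrt(sum(un^2))
            H[j, ] <- sqrt(s$d[j] * nneg) * vn / sqrt(sum(vn^2))
        }
    }
    mu <- mean(A)
    W[W == 0] <- mu; H[H == 0] <- mu
    list(W = W, H = H)
}

#' Factorize spatial abundances into microenvironments by NMF
#'
#' Minimizes the Frobenius reconstruction error ||A - W H|| over nonnegative
#' W (spot weights) and H (factor x cell-type loadings) with multiplicative
#' updates from a deterministic nonnegative-double-SVD start, so results are
#' reproducible for a given seed. The atlas setting is d = 10 factors.
#' Loadings are also returned normalized per cell type (each type's loading
#' fractions across factors sum to 1), which is the scale on which
#' microenvironment membership is called.
#'
#' @param sa a \linkS4class{SpatialAbundance} (nonnegative).
#' @param d number of factors; must be below min(spots, types).
#' @param seed integer; fixes the random restarts, making the result
#'   reproducible.
#' @param maxIter,tol multiplicative-update stopping rule.
#' @param nRestarts random restarts tried in addition to the deterministic
#'   NNDSVD start; the solution with the lowest reconstruction error wins
#'   (multiplicative updates only find local minima).
#' @return a \linkS4class{MicroenvironmentSet}.
#' @export
factorizeNMF <- function(sa, d = 10, seed = 0L, maxIter = 2000, tol = 1e-8,
                         nRestarts = 4) {
    A <- abundance(sa)
    if (d <= 0) stop("d must be positive")
    if (d >= min(dim(A))) stop("d must be below min(spots, celltypes)")
    if (any(A < 0)) stop("abundances must be nonnegative")
    set.seed(seed)
    eps <- 1e-12
    run <- function(W, H) {
        errOld <- Inf
        for (it in seq_len(maxIter)) {
            H <- H * (crossprod(W, A) + eps) / (crossprod(W) %*% H + eps)
            W <- W * (A %*% t(H) + eps) / (W %*% tcrossprod(H) + eps)
            if (it %% 10 == 0) {
                err <- sqrt(sum((A - W %*% H)^2))
                if (is.finite(errOld) && errOld - err < tol * errOld) break
                errOld <- err
            }
        }
        list(W = W, H = H, err = sqrt(sum((A - W %*% H)^2)))
    }
    init <- .nndsvda(A, d)
    best <- run(init$W, init$H)
    mu <- sqrt(mean(A) / d)
    for (rs in seq_len(nRestarts)) {
        cand <- run(matrix(stats::rexp(nrow(A) * d, 1 / mu), nrow(A), d),
                    matrix(stats::rexp(d * ncol(A), 1 / mu), d, ncol(A)))
        if (cand$err < best$err) best <- cand
    }
    W <- best$W; H <- best$H
    ## fix the scale indeterminacy: rows of H to unit L2 norm
    nrm <- sqrt(rowSums(H^2))
    nrm[nrm == 0] <- 1
    H <- H / nrm
    W <- W * rep(nrm, each = nrow(W))
    dimnames(H) <- list(paste0("F", seq_len(d)), colnames(A))
    dimnames(W) <- list(rownames(A), rownames(H))
    cs <- colSums(H)
    Hnorm <- sweep(H, 2, ifelse(cs > 0, cs, 1), "/")
    new("MicroenvironmentSet", W = W, H = H, Hnorm = Hnorm,
        d = as.integer(d), membership = list())
}

#' Call microenvironment membership and retain group factors
#'
#' A cell type belongs to a microenvironment when its loading fraction for
#' that factor is strictly over \code{fracThreshold} (atlas rule: 0.2).
#' When a cell-type group is supplied (e.g. the mature T cell types for the
#' thymic medulla analysis), only factors whose summed group fractions are
#' strictly above \code{groupSumThreshold} (atlas rule: 0.8) are retained.
#'
#' @param me a \linkS4class{MicroenvironmentSet}.
#' @param fracThreshold membership cut on the loading fraction (0.2).
#' @param group optional character vector of cell types forming the group.
#' @param groupSumThreshold retention cut on the group fraction sum (0.8).
#' @return \code{me} with the \code{membership} slot filled;
#'   \code{attr(membership(me), "retainedFactors")} when a group is given.
#' @export
microenvironmentMembership <- function(me, fracThreshold = 0.2,
                                       group = NULL,
                                       groupSumThreshold = 0.8) {
    Hn <- loadingFractions(me)
    memb <- lapply(seq_len(nrow(Hn)), function(f)
        colnames(Hn)[Hn[f, ] > fracThreshold])
    names(memb) <- rownames(Hn)
    retained <- seq_len(nrow(Hn))
    if (!is.null(group)) {
        gsum <- rowSums(Hn[, intersect(group, colnames(Hn)), drop = FALSE])
        retained <- which(gsum > groupSumThreshold)
    }
    attr(memb, "retainedFactors") <- retained
    me@membership <- memb
    me
}

#' @rdname microenvironmentMembership
#' @param x a \code{MicroenvironmentSet} with called membership
#' @export
membership <- function(x) x@membership

#' Assign spots to microenvironments by the per-slide quantile rule
#'
#' A spot carries a microenvironment when its factor weight is strictly
#' above the \code{q}-quantile of that factor's weights across all spots of
#' the same slide (atlas rule: 90% quantile). A spot can carry several
#' microenvironments; with constant factor values no spot exceeds the
#' quantile and none is assigned.
#'
#' @param me a \linkS4class{MicroenvironmentSet}.
#' @param sa the \linkS4class{SpatialAbundance} it was fitted on.
#' @param q assignment quantile (default 0.90).
#' @return logical spots x factors matrix.
#' @export
assignSpotsToMicroenv <- function(me, sa, q = 0.90) {
    W <- spotWeights(me)
    slides <- slideId(sa)
    if (nrow(W) != length(slides))
        stop("me and sa disagree on spot number")
    small <- names(which(table(slides) < 10))
    if (length(small))
        warning("slide(s) with < 10 spots give unstable quantiles: ",
                paste(small, collapse = ", "))
    out <- matrix(FALSE, nrow(W), ncol(W), dimnames = dimnames(W))
    for (s in unique(slides)) {
        i <- slides == s
        thr <- apply(W[i, , drop = FALSE], 2, stats::quantile,
                     probs = q, names = FALSE)
        out[i, ] <- sweep(W[i, , drop = FALSE], 2, thr, ">")
    }
    out
}

#' Match recovered factors to planted factors by cosine similarity
#'
#' One-to-one matching of two loading matrices maximizing the summed cosine
#' similarity of matched rows (the assignment problem, solved as a
#' maximum-weight bipartite matching). Used to score NMF recovery against a
#' planted truth.
#'
#' @param Hhat,Htrue factor x cell-type loading matrices with equal row
#'   counts.
#' @return data.frame: recovered factor, matched true factor, cosine.
#' @export
#' @importFrom igraph graph_from_biadjacency_matrix max_bipartite_match
matchFactors <- function(Hhat, Htrue) {
    stopifnot(nrow(Hhat) == nrow(Htrue), ncol(Hhat) == ncol(Htrue))
    unit <- function(M) M / pmax(sqrt(rowSums(M^2)), 1e-12)
    S <- unit(Hhat) %*% t(unit(Htrue))
    ## shift weights to be positive; matching maximizes total weight
    Spos <- S - min(S) + 1e-9
    dimnames(Spos) <- list(paste0("rec", seq_len(nrow(S))),
                           paste0("tru", seq_len(ncol(S))))
    g <- igraph::graph_from_biadjacency_matrix(Spos, weighted = TRUE)
    m <- igraph::max_bipartite_match(g)
    matched <- as.integer(sub("^tru", "", m$matching[seq_len(nrow(S))]))
    data.frame(factor = seq_len(nrow(S)), true_factor = matched,
               cosine = S[cbind(seq_len(nrow(S)), matched)])
}
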