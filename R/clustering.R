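## Fuzzy c-means clustering of regulated transcript profiles. Soft
## partitioning reduces the impact of noise: each profile carries a
## membership to every cluster, controlled by the fuzzifier m (1.7 here,
## the value used for the time-course analysis).

#' Standardize profiles to z-scores across conditions
#'
#' @param x numeric matrix, profiles x conditions.
#' @return matrix with each row centred and scaled to unit sd; zero-variance
#'   rows are set to 0.
#' @export
standardizeProfiles <- function(x) {
    mu <- rowMeans(x)
    s <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1L))
    out <- (x - mu) / ifelse(s > 0, s, 1)
    out[s == 0, ] <- 0
    out
}

#' Fuzzy c-means clustering
#'
#' Standard FCM alternation with Euclidean distances: memberships
#' \code{u_ij} proportional to \code{(1/d_ij^2)^(1/(m-1))} normalized per
#' row, centroids the \code{u^m}-weighted profile means, iterated until the
#' maximum centroid shift drops below \code{tol} or \code{maxIter} is
#' reached. A profile coinciding with a centroid takes membership 1 there
#' (the zero-distance limit; split equally over tied centroids). Initial
#' centroids are \code{c} distinct profiles drawn by the seeded RNG.
#'
#' @param x numeric matrix of profiles (rows) to cluster; standardize per
#'   profile first (\code{\link{standardizeProfiles}}) for the usual
#'   z-score semantics.
#' @param c number of clusters (2 <= c < nrow(x)).
#' @param m fuzzifier, > 1; default 1.7.
#' @param tol convergence threshold on the centroid shift (default 1e-6).
#' @param maxIter iteration cap (default 300).
#' @param rngSeed integer seed for the centroid initialization.
#' @return A \linkS4class{FuzzyClusterResult}.
#' @export
fuzzyCMeans <- function(x, c, m = 1.7, tol = 1e-6, maxIter = 300L,
                        rngSeed = 1L) {
    x <- as.matrix(x)
    if (m <= 1) stop("fuzzifier m must be > 1")
    if (c < 2L || c >= nrow(x)) stop("need n > c >= 2")
    withSeed(rngSeed, {
        uniq <- x[!duplicated(x), , drop = FALSE]
        if (nrow(uniq) < c)
            stop("fewer than c distinct profiles")
        cen <- uniq[sample(nrow(uniq), c), , drop = FALSE]
        rownames(cen) <- paste0("C", seq_len(c))
        obj <- numeric(0)
        converged <- FALSE
        iter <- 0L
        expo <- 1 / (m - 1)
        while (iter < maxIter) {
            iter <- iter + 1L
            d2 <- outer(rowSums(x^2), rep(1, c)) +
                outer(rep(1, nrow(x)), rowSums(cen^2)) -
                2 * x %*% t(cen)
            d2[d2 < 0] <- 0
            u <- matrix(0, nrow(x), c)
            zero <- d2 <= .Machine$double.eps
            hasZero <- rowSums(zero) > 0L
            if (any(!hasZero)) {
                ## log-space for numerical stability when m is close to 1
                lw <- -expo * log(d2[!hasZero, , drop = FALSE])
                lw <- lw - apply(lw, 1, max)
                w <- exp(lw)
                u[!hasZero, ] <- w / rowSums(w)
            }
            if (any(hasZero)) {
                zi <- zero[hasZero, , drop = FALSE]
                u[hasZero, ] <- zi / rowSums(zi)
            }
            obj <- c(obj, sum(u^m * d2))
            um <- u^m
            newCen <- (t(um) %*% x) / colSums(um)
            shift <- max(abs(newCen - cen))
            cen <- newCen
            rownames(cen) <- paste0("C", seq_len(c))
            if (shift < tol) { converged <- TRUE; break }
        }
        dimnames(u) <- list(rownames(x), rownames(cen))
        new("FuzzyClusterResult", centroids = cen, membership = u,
            objective = obj, nIter = iter, converged = converged)
    })
}

#' Alpha-core cluster assignment
#'
#' A profile belongs to the alpha-core of its best cluster iff its maximal
#' membership reaches \code{alpha}; profiles below \code{alpha} everywhere
#' stay unassigned.
#'
#' @param result a \linkS4class{FuzzyClusterResult}.
#' @param alpha membership threshold in [0, 1] (default 0.5).
#' @return data.frame with columns id, cluster (NA when unassigned),
#'   membership, inAlphaCore.
#' @export
alphaCore <- function(result, alpha = 0.5) {
    if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
    u <- membership(result)
    best <- max.col(u, ties.method = "first")
    bestVal <- u[cbind(seq_len(nrow(u)), best)]
    core <- bestVal >= alpha
    data.frame(id = rownames(u),
               cluster = ifelse(core, best, NA_integer_),
               membership = bestVal, inAlphaCore = core,
               row.names = NULL, stringsAsFactors = FALSE)
}
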