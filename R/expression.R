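## Detection-call filtering and differential expression versus the donor
## fibroblast. Probes are opaque identifiers; one row = one probe throughout
## (no probe-to-gene collapsing).

#' Quantile-normalize a matrix of (raw- or log-scale) intensities
#'
#' Thin wrapper around \code{limma::normalizeQuantiles} keeping probe order.
#' Idempotent: a matrix whose columns already share one empirical
#' distribution is returned unchanged. With a single column the step is the
#' identity.
#'
#' @param x numeric matrix, probes x samples.
#' @return matrix of the same shape.
#' @export
quantileNormalize <- function(x) {
    if (ncol(x) < 2L) return(x)
    out <- limma::normalizeQuantiles(x)
    dimnames(out) <- dimnames(x)
    out
}

#' Normalize raw bead-array intensities
#'
#' log2-transforms strictly positive raw intensities and quantile-normalizes
#' across samples (the stand-in for the original variance-stabilizing
#' background correction, whose parameters are not part of this pipeline).
#'
#' @param raw numeric matrix of raw-scale intensities (> 0), probes x
#'   samples, with probe ids as rownames.
#' @param detectionP matching matrix of detection p-values.
#' @param group,replicate per-sample annotation (see
#'   \code{\link{ReprogExperiment}}).
#' @param log2Transform set FALSE when \code{raw} is already on the log2
#'   scale (only the quantile step is then applied).
#' @return A \linkS4class{ReprogExperiment}.
#' @export
normalizeExpression <- function(raw, detectionP, group, replicate,
                                log2Transform = TRUE) {
    if (log2Transform) {
        bad <- which(raw <= 0, arr.ind = TRUE)
        if (nrow(bad))
            stop(sprintf("non-positive intensity for probe '%s', sample '%s'",
                         rownames(raw)[bad[1, 1]], colnames(raw)[bad[1, 2]]))
        raw <- log2(raw)
    }
    ReprogExperiment(quantileNormalize(raw), detectionP, group, replicate)
}

#' @rdname callDetection
#' @export
setGeneric("callDetection",
           function(object, threshold = 0.01) standardGeneric("callDetection"))

#' Present/absent detection calls and the duplicate-present filter
#'
#' A probe is "present" in a sample iff its detection p-value is strictly
#' below \code{threshold} (p equal to the threshold is absent). The analysis
#' set keeps probes present in \emph{both} duplicates of at least one sample
#' group; for a group with a single replicate the rule degenerates to
#' presence in that sample (a warning is emitted).
#'
#' @param object a \linkS4class{ReprogExperiment}.
#' @param threshold strict detection cutoff, default 0.01.
#' @return A \linkS4class{DetectionCalls}.
#' @export
setMethod("callDetection", "ReprogExperiment",
          function(object, threshold = 0.01) {
    present <- detectionP(object) < threshold
    grp <- sampleGroups(object)
    singles <- names(which(table(grp) == 1L))
    if (length(singles))
        warning("group(s) with a single replicate (duplicate-present rule ",
                "degenerates to single-sample presence): ",
                paste(singles, collapse = ", "))
    groupPresent <- vapply(unique(grp), function(g)
        rowSums(!present[, grp == g, drop = FALSE]) == 0L,
        logical(nrow(present)))
    keep <- rownames(present)[rowSums(groupPresent) > 0L]
    new("DetectionCalls", present = present, analysisSet = keep,
        threshold = threshold)
})

#' Group-level presence (present in every replicate of the group)
#'
#' @param calls a \linkS4class{DetectionCalls}.
#' @param groups per-sample group labels in column order of the call matrix.
#' @return logical matrix, probes x groups.
#' @export
groupPresence <- function(calls, groups) {
    present <- presentCalls(calls)
    vapply(unique(groups), function(g)
        rowSums(!present[, groups == g, drop = FALSE]) == 0L,
        logical(nrow(present)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Own implementation of the BH step-up procedure: adjusted p-value of the
#' i-th order statistic is \code{min_{j >= i} (m/j) p_(j)}, capped at 1.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values in input order.
#' @export
adjustBH <- function(p) {
    if (anyNA(p) || any(p < 0) || any(p > 1))
        stop("p-values must lie in [0, 1]")
    m <- length(p)
    if (m <= 1L) return(p)
    o <- order(p)
    adj <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
    adj[order(o)]
}

estimatePrior <- function(s2, df) {
    ## method-of-moments fit of the scaled inverse-chi-square variance prior:
    ## s2 ~ s0^2 * F(df, d0); the squared coefficient of variation of s2
    ## identifies d0, the mean then gives s0^2
    s2 <- s2[is.finite(s2)]
    m1 <- mean(s2)
    if (m1 <= 0 || length(s2) < 3L)
        return(list(d0 = 0, s02 = m1))
    r <- stats::var(s2) / m1^2
    if (r * df <= 2) {
        d0 <- Inf
        s02 <- m1
    } else {
        d0 <- (2 * df + 4 * r * df - 4) / (r * df - 2)
        if (d0 <= 4) d0 <- 4.001     # moment solution valid for d0 > 4
        s02 <- m1 * (d0 - 2) / d0
    }
    list(d0 = d0, s02 = s02)
}

#' Moderated-t differential expression versus the donor group
#'
#' For each analysis-set probe, the log2 fold change is the contrast-group
#' mean minus the donor mean. Per-probe pooled variances are shrunk towards
#' a common prior estimated by method of moments (empirical-Bayes moderated
#' t with augmented degrees of freedom); \code{priorDf = 0} gives the
#' ordinary pooled two-sample t. P-values are two-sided and adjusted by
#' Benjamini-Hochberg across the analysis set. A probe is \emph{regulated}
#' when \code{adjPValue < pAdjThreshold} and |log2FC| > log2(fcThreshold).
#'
#' @param object a \linkS4class{ReprogExperiment}.
#' @param calls a \linkS4class{DetectionCalls} restricting probes to the
#'   analysis set.
#' @param contrast group label compared against the donor.
#' @param donorGroup donor group label (default \code{"donor"}).
#' @param priorDf prior degrees of freedom: \code{NULL} (default) estimates
#'   them from the variance distribution; 0 disables moderation.
#' @param pAdjThreshold,fcThreshold regulation thresholds (defaults 0.05 and
#'   1.5-fold).
#' @return data.frame with columns probe, contrast, logFC, t, df, pValue,
#'   adjPValue, regulated, direction.
#' @export
setGeneric("differentialExpression",
           function(object, calls, contrast, donorGroup = "donor",
                    priorDf = NULL, pAdjThreshold = 0.05, fcThreshold = 1.5)
               standardGeneric("differentialExpression"))

#' @rdname differentialExpression
#' @export
setMethod("differentialExpression", "ReprogExperiment",
          function(object, calls, contrast, donorGroup = "donor",
                   priorDf = NULL, pAdjThreshold = 0.05, fcThreshold = 1.5) {
    grp <- sampleGroups(object)
    if (!contrast %in% grp || !donorGroup %in% grp)
        stop("contrast and donor groups must exist in the experiment")
    x <- intensities(object)[analysisSet(calls), , drop = FALSE]
    a <- x[, grp == contrast, drop = FALSE]
    b <- x[, grp == donorGroup, drop = FALSE]
    n1 <- ncol(a); n2 <- ncol(b)
    if (n1 < 2L || n2 < 2L)
        stop("both groups need at least 2 samples")
    logFC <- rowMeans(a) - rowMeans(b)
    df <- n1 + n2 - 2L
    s2 <- (rowSums((a - rowMeans(a))^2) + rowSums((b - rowMeans(b))^2)) / df
    if (is.null(priorDf)) {
        pr <- estimatePrior(s2, df)
    } else if (priorDf == 0) {
        pr <- list(d0 = 0, s02 = 0)
    } else {
        pr <- list(d0 = priorDf, s02 = estimatePrior(s2, df)$s02)
    }
    if (is.finite(pr$d0)) {
        s2mod <- (pr$d0 * pr$s02 + df * s2) / (pr$d0 + df)
    } else s2mod <- rep(pr$s02, length(s2))
    dfTotal <- df + pr$d0
    tt <- logFC / sqrt(s2mod * (1 / n1 + 1 / n2))
    if (any(s2mod == 0)) {
        warning(sum(s2mod == 0), " zero-variance probe(s) with no prior: ",
                "t undefined, reported as NA")
        tt[s2mod == 0] <- NA_real_
    }
    pRaw <- 2 * stats::pt(abs(tt), df = dfTotal, lower.tail = FALSE)
    pAdj <- rep(NA_real_, length(pRaw))
    ok <- !is.na(pRaw)
    pAdj[ok] <- adjustBH(pRaw[ok])
    regulated <- !is.na(pAdj) & pAdj < pAdjThreshold &
        abs(logFC) > log2(fcThreshold)
    direction <- ifelse(!regulated, "none",
                        ifelse(logFC > 0, "up", "down"))
    data.frame(probe = rownames(x), contrast = contrast, logFC = logFC,
               t = tt, df = dfTotal, pValue = pRaw, adjPValue = pAdj,
               regulated = regulated, direction = direction,
               row.names = NULL, stringsAsFactors = FALSE)
})

#' Differential expression for all five contrasts
#'
#' @param object,calls,donorGroup,priorDf,pAdjThreshold,fcThreshold see
#'   \code{\link{differentialExpression}}.
#' @param contrasts ordered contrast labels (default the study's
#'   24h/48h/72h/iPS/ES versus donor).
#' @return single data.frame stacking the per-contrast results.
#' @export
differentialExpressionAll <- function(object, calls,
                                      contrasts = c("24h", "48h", "72h",
                                                    "iPS", "ES"),
                                      donorGroup = "donor", priorDf = NULL,
                                      pAdjThreshold = 0.05,
                                      fcThreshold = 1.5) {
    do.call(rbind, lapply(contrasts, function(ct)
        differentialExpression(object, calls, ct, donorGroup = donorGroup,
                               priorDf = priorDf,
                               pAdjThreshold = pAdjThreshold,
                               fcThreshold = fcThreshold)))
}

#' Regulation-profile strings
#'
#' Encodes, per probe, a 5-character 0/1 string whose i-th character is '1'
#' iff the probe is regulated in the i-th contrast (order 24h, 48h, 72h,
#' iPS, ES by default).
#'
#' @param de stacked DE table from \code{\link{differentialExpressionAll}}.
#' @param contrasts contrast order defining string positions.
#' @return data.frame with columns probe, profile.
#' @export
regulationProfile <- function(de, contrasts = c("24h", "48h", "72h",
                                                "iPS", "ES")) {
    missing <- setdiff(contrasts, unique(de$contrast))
    if (length(missing))
        stop("missing contrast(s): ", paste(missing, collapse = ", "))
    probes <- unique(de$probe)
    bits <- vapply(contrasts, function(ct) {
        d <- de[de$contrast == ct, ]
        reg <- setNames(d$regulated, d$probe)[probes]
        reg[is.na(reg)] <- FALSE
        reg
    }, logical(length(probes)))
    data.frame(probe = probes,
               profile = apply(bits, 1, function(b)
                   paste(as.integer(b), collapse = "")),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Project samples onto the first two principal components
#'
#' Probe-wise mean-centred PCA of the sample vectors; no scaling. Component
#' 1 carries at least as much variance as component 2.
#'
#' @param object a \linkS4class{ReprogExperiment} or a probes x samples
#'   matrix.
#' @return data.frame with columns sample, group (when available), PC1, PC2;
#'   attribute \code{"varianceExplained"} holds the per-component variance
#'   fractions.
#' @export
pcaProjection <- function(object) {
    if (is(object, "ReprogExperiment")) {
        x <- intensities(object)
        grp <- sampleGroups(object)
    } else {
        x <- object
        grp <- NULL
    }
    if (ncol(x) < 3L)
        stop("at least 3 samples required for a 2-component projection")
    pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
    out <- data.frame(sample = colnames(x), PC1 = pc$x[, 1], PC2 = pc$x[, 2],
                      row.names = NULL, stringsAsFactors = FALSE)
    if (!is.null(grp)) out$group <- grp
    attr(out, "varianceExplained") <- pc$sdev^2 / sum(pc$sdev^2)
    out
}
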