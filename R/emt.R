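## Seed-based EMT-suppression signature. A small list of positive EMT genes
## seeds a genome-wide co-expression ranking; the ranking is validated by a
## leave-out recovery test with a cumulative-binomial null, and EMT
## suppression during reprogramming is quantified per cell state by a
## Spearman rank-correlation statistic and a binomial over-representation
## test against the most down-regulated genes.

#' The packaged positive-EMT seed gene list
#'
#' 36 key up-regulated EMT genes (mesenchymal markers, EMT transcription
#' factors and matrix remodelling enzymes) shipped as a GMT fixture.
#'
#' @return character vector of gene symbols.
#' @export
emtSeedGenes <- function() {
    gmt <- readGMT(system.file("extdata", "emt_seed_genes.gmt",
                               package = "earlyReprog"))
    gmt[["EMT_UP_SEED"]]
}

#' Seed-based genome-wide ranking
#'
#' Scores every gene of a compendium by its mean Pearson correlation with
#' the seed-gene profiles (self-correlation excluded for seed genes) and
#' ranks all genes by decreasing similarity; ties are broken
#' lexicographically by gene id. Samples (columns) are standardized to
#' zero mean / unit variance first, so the ranking is invariant to sample
#' order and to affine rescaling of any single sample (array-level scale
#' effects). Zero-variance genes get similarity 0; seeds absent from the
#' compendium are dropped, both with a warning.
#'
#' @param compendium numeric matrix, genes x samples (>= 3 samples), gene
#'   ids as rownames.
#' @param seeds character vector of seed gene ids.
#' @param method correlation type, \code{"pearson"} (default) or
#'   \code{"spearman"}.
#' @return data.frame with columns rank, gene, similarity (rank 1 = most
#'   seed-like); a permutation of the compendium's gene universe.
#' @export
seedRank <- function(compendium, seeds, method = c("pearson", "spearman")) {
    method <- match.arg(method)
    if (ncol(compendium) < 3L) stop("at least 3 samples required")
    sds <- apply(compendium, 1, stats::sd)   # flat genes, pre-scaling
    colSd <- apply(compendium, 2, stats::sd)
    keepScale <- ifelse(colSd > 0, colSd, 1)
    compendium <- sweep(sweep(compendium, 2, colMeans(compendium)),
                        2, keepScale, "/")
    genes <- rownames(compendium)
    missing <- setdiff(seeds, genes)
    if (length(missing)) {
        warning(length(missing), " seed(s) absent from the compendium: ",
                paste(utils::head(missing, 5), collapse = ", "))
        seeds <- intersect(seeds, genes)
    }
    flat <- sds == 0
    if (any(flat))
        warning(sum(flat), " zero-variance gene(s); similarity set to 0")
    liveSeeds <- setdiff(seeds, genes[flat])
    if (length(liveSeeds) == 0L) stop("empty effective seed set")
    if (method == "spearman")
        compendium <- t(apply(compendium, 1, rank))
    cc <- suppressWarnings(
        stats::cor(t(compendium[liveSeeds, , drop = FALSE]),
                   t(compendium)))            # seeds x genes
    cc[, flat] <- 0
    sim <- colSums(cc)
    nEff <- rep(length(liveSeeds), length(genes))
    names(nEff) <- genes
    isSeed <- genes %in% liveSeeds
    sim[isSeed] <- sim[isSeed] - 1            # drop the self-correlation
    nEff[isSeed] <- nEff[isSeed] - 1L
    sim <- ifelse(nEff > 0, sim / nEff, 0)
    sim[flat] <- 0
    o <- order(-sim, genes)
    data.frame(rank = seq_along(genes), gene = genes[o],
               similarity = sim[o], row.names = NULL,
               stringsAsFactors = FALSE)
}

#' Leave-out recovery test of a seed ranking
#'
#' Repeatedly removes a fraction of the seeds, re-ranks the genome with the
#' reduced seed set, and records in which equal-width rank bin (deciles of
#' the universe by default) each left-out seed lands. If the ranking is
#' informative the left-out seeds pile up in the first bin; the p-value is
#' the upper tail P(X >= x1) of X ~ Binomial(nDraws, 1/nBins) at the
#' observed first-bin count.
#'
#' @param compendium,seeds as in \code{\link{seedRank}}.
#' @param leaveOutFraction fraction of seeds removed per repeat (ceil'd to
#'   at least one gene).
#' @param nRepeats number of leave-out rounds.
#' @param nBins number of equal-width rank bins (default 10).
#' @param rngSeed integer seed.
#' @return list with binCounts (length nBins), nDraws, pValue.
#' @export
recoveryTest <- function(compendium, seeds, leaveOutFraction = 0.1,
                         nRepeats = 20L, nBins = 10L, rngSeed = 1L) {
    if (nBins < 2L) stop("nBins must be at least 2")
    if (nRepeats < 1L) stop("nRepeats must be at least 1")
    seeds <- intersect(seeds, rownames(compendium))
    nOut <- as.integer(ceiling(leaveOutFraction * length(seeds)))
    if (nOut < 1L || nOut >= length(seeds))
        stop("leaveOutFraction must leave out >= 1 and keep >= 1 seed")
    N <- nrow(compendium)
    width <- N / nBins
    withSeed(rngSeed, {
        bins <- integer(nBins)
        for (r in seq_len(nRepeats)) {
            out <- sample(seeds, nOut)
            rk <- seedRank(compendium, setdiff(seeds, out))
            pos <- match(out, rk$gene)
            b <- pmin(nBins, ceiling(pos / width))
            bins <- bins + tabulate(b, nBins)
        }
        nDraws <- nOut * nRepeats
        p <- stats::pbinom(bins[1] - 1L, nDraws, 1 / nBins,
                           lower.tail = FALSE)
        list(binCounts = bins, nDraws = nDraws, pValue = p)
    })
}

#' Spearman rank-correlation EMT-suppression statistic
#'
#' Takes the \code{topN} most significantly down-regulated genes of a
#' contrast (rank 1 = most down, by ascending moderated t), pairs each
#' gene's down-regulation rank with its position in the EMT-ranked genome,
#' and reports the Spearman correlation of the paired ranks. Positive rho
#' means EMT-like genes are preferentially down-regulated; the p-value uses
#' the two-sided large-sample t approximation.
#'
#' @param ranked output of \code{\link{seedRank}}.
#' @param de stacked DE table (see
#'   \code{\link{differentialExpressionAll}}); probe/gene ids must live in
#'   the same namespace as \code{ranked$gene}.
#' @param contrast contrast label selecting the cell state.
#' @param topN number of down-regulated genes used; \code{NULL} (default)
#'   takes all significantly down-regulated genes.
#' @param significantOnly restrict to regulated probes (default TRUE); set
#'   FALSE to rank all probes by t regardless of significance (used for
#'   null calibration).
#' @return data.frame row: state, n, rho, pSpearman.
#' @export
suppressionRankCorrelation <- function(ranked, de, contrast, topN = NULL,
                                       significantOnly = TRUE) {
    d <- de[de$contrast == contrast & !is.na(de$t), ]
    if (significantOnly) d <- d[d$regulated & d$direction == "down", ]
    d <- d[order(d$t), ]
    if (!is.null(topN)) d <- utils::head(d, topN)
    pos <- match(d$probe, ranked$gene)
    if (anyNA(pos)) {
        warning(sum(is.na(pos)), " down-regulated gene(s) absent from the ",
                "ranked list; dropped")
        d <- d[!is.na(pos), ]
        pos <- pos[!is.na(pos)]
    }
    n <- nrow(d)
    if (n < 3L) stop("fewer than 3 paired genes for contrast ", contrast)
    downRank <- seq_len(n)
    rho <- stats::cor(downRank, pos, method = "spearman")
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
    data.frame(state = contrast, n = n, rho = rho, pSpearman = p,
               stringsAsFactors = FALSE)
}

#' Binomial over-representation of top EMT genes among down-regulated genes
#'
#' With x the overlap between the top-k genes of the EMT ranking and the
#' top-m most down-regulated genes, reports P(X >= x) for
#' X ~ Binomial(m, k/N) over the N-gene universe.
#'
#' @param ranked output of \code{\link{seedRank}}.
#' @param de,contrast as in \code{\link{suppressionRankCorrelation}}.
#' @param topKEmt number of top EMT-ranked genes (default 100).
#' @param topMDown number of most down-regulated genes; \code{NULL}
#'   (default) takes all significantly down-regulated genes.
#' @param significantOnly see \code{\link{suppressionRankCorrelation}}.
#' @return data.frame row: state, overlap, topKEmt, topMDown, pBinomial.
#' @export
overrepresentationBinomial <- function(ranked, de, contrast, topKEmt = 100L,
                                       topMDown = NULL,
                                       significantOnly = TRUE) {
    d <- de[de$contrast == contrast & !is.na(de$t), ]
    if (significantOnly) d <- d[d$regulated & d$direction == "down", ]
    d <- d[order(d$t), ]
    if (!is.null(topMDown)) d <- utils::head(d, topMDown)
    if (nrow(d) == 0L) stop("empty down-regulated list for ", contrast)
    N <- nrow(ranked)
    topEmt <- utils::head(ranked$gene, topKEmt)
    x <- length(intersect(topEmt, d$probe))
    m <- nrow(d)
    p <- stats::pbinom(x - 1L, m, topKEmt / N, lower.tail = FALSE)
    data.frame(state = contrast, overlap = x, topKEmt = topKEmt,
               topMDown = m, pBinomial = p, stringsAsFactors = FALSE)
}

#' Table of EMT-suppression statistics across cell states
#'
#' Convenience wrapper producing one row per contrast with the Spearman
#' suppression statistic and the binomial over-representation p-value
#' side by side.
#'
#' @param ranked,de see above.
#' @param contrasts ordered cell-state labels.
#' @param topKEmt,topN,significantOnly passed through.
#' @return data.frame: state, n, rho, pSpearman, overlap, pBinomial.
#' @export
emtSignatureTable <- function(ranked, de,
                              contrasts = c("24h", "48h", "72h",
                                            "iPS", "ES"),
                              topKEmt = 100L, topN = NULL,
                              significantOnly = TRUE) {
    rows <- lapply(contrasts, function(ct) {
        sp <- suppressionRankCorrelation(ranked, de, ct, topN = topN,
                                         significantOnly = significantOnly)
        bi <- overrepresentationBinomial(ranked, de, ct, topKEmt = topKEmt,
                                         topMDown = topN,
                                         significantOnly = significantOnly)
        cbind(sp, bi[, c("overlap", "pBinomial")])
    })
    do.call(rbind, rows)
}
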