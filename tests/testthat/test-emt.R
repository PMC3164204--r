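moduleCompendium <- function(seed = 1L, nGenes = 546L, nSamples = 40L,
                             nSeeds = 36L, nExtra = 10L, rho = 0.9) {
    seeds <- sprintf("SEED%02d", seq_len(nSeeds))
    extra <- sprintf("XTRA%02d", seq_len(nExtra))
    comp <- simulateCompendium(nGenes, nSamples,
                               seedModule = c(seeds, extra),
                               moduleCorrelation = rho, rngSeed = seed)
    list(comp = comp, seeds = seeds, extra = extra)
}

test_that("seed ranking places the planted module on top", {
    d <- moduleCompendium(seed = 2L)   # 46 module genes + 500 background
    rk <- seedRank(d$comp, d$seeds)
    expect_setequal(rk$gene, rownames(d$comp))
    expect_identical(nrow(rk), nrow(d$comp))
    expect_true(all(diff(rk$similarity) <= 1e-12))
    top <- rk$gene[1:46]
    expect_setequal(top, c(d$seeds, d$extra))
})

test_that("an exact copy of a seed profile outranks all background genes", {
    d <- moduleCompendium(seed = 3L, nGenes = 120L, nSeeds = 8L,
                          nExtra = 0L, rho = 0.95)
    comp <- rbind(d$comp, COPY = d$comp[d$seeds[1], ])
    rk <- seedRank(comp, d$seeds)
    bg <- setdiff(rownames(comp), c(d$seeds, "COPY"))
    expect_lt(match("COPY", rk$gene), min(match(bg, rk$gene)))
})

test_that("seed ranking is invariant to sample order and per-sample
           rescaling", {
    d <- moduleCompendium(seed = 4L, nGenes = 80L, nSeeds = 6L,
                          nExtra = 0L)
    rk <- seedRank(d$comp, d$seeds)
    perm <- d$comp[, sample(ncol(d$comp))]
    expect_identical(seedRank(perm, d$seeds)$gene, rk$gene)
    scaled <- d$comp
    scaled[, 3] <- scaled[, 3] * 7 + 2
    rk2 <- seedRank(scaled, d$seeds)
    expect_identical(rk2$gene, rk$gene)
    expect_equal(rk2$similarity, rk$similarity, tolerance = 1e-9)
})

test_that("seed ranking handles degenerate genes and missing seeds", {
    d <- moduleCompendium(seed = 5L, nGenes = 60L, nSeeds = 5L,
                          nExtra = 0L)
    comp <- rbind(d$comp, FLAT = rep(3, ncol(d$comp)))
    expect_warning(rk <- seedRank(comp, d$seeds), "zero-variance")
    expect_equal(rk$similarity[rk$gene == "FLAT"], 0)
    expect_warning(seedRank(d$comp, c(d$seeds, "NOSUCH")), "absent")
    expect_error(suppressWarnings(seedRank(d$comp, "NOSUCH")),
                 "empty effective seed set")
})

test_that("recovery test reproduces the closed-form extreme case", {
    ## tight module: every left-out seed recovers in the first decile;
    ## 36 seeds at 10% leave-out = 4 per repeat, 5 repeats = 20 draws
    d <- moduleCompendium(seed = 6L, nGenes = 500L, rho = 0.95)
    rec <- recoveryTest(d$comp, d$seeds, leaveOutFraction = 0.1,
                        nRepeats = 5L, nBins = 10L, rngSeed = 9L)
    expect_identical(sum(rec$binCounts), rec$nDraws)
    expect_identical(rec$nDraws, 20L)
    expect_identical(rec$binCounts[1], 20L)
    expect_equal(rec$pValue, 1e-20, tolerance = 1e-10)
})

test_that("recovery p equals the direct-summation tail oracle", {
    for (s in 1:8) {
        set.seed(s)
        d <- moduleCompendium(seed = s + 50L, nGenes = 150L, nSeeds = 10L,
                              nExtra = 0L, rho = runif(1, 0, 0.8))
        rec <- recoveryTest(d$comp, d$seeds, leaveOutFraction = 0.2,
                            nRepeats = 4L, nBins = 5L, rngSeed = s)
        expect_identical(sum(rec$binCounts), rec$nDraws)
        expect_equal(rec$pValue,
                     bruteBinomTail(rec$binCounts[1], rec$nDraws, 1 / 5),
                     tolerance = 1e-10)
    }
    d <- moduleCompendium(seed = 1L, nGenes = 100L, nSeeds = 5L,
                          nExtra = 0L)
    expect_error(recoveryTest(d$comp, d$seeds, nBins = 1L), "nBins")
    expect_error(recoveryTest(d$comp, d$seeds, nRepeats = 0L), "nRepeats")
})

fakeDE <- function(probes, tstat, contrast = "72h") {
    data.frame(probe = probes, contrast = contrast, logFC = -abs(tstat),
               t = tstat, pValue = 0.001, adjPValue = 0.001,
               regulated = TRUE, direction = "down",
               stringsAsFactors = FALSE)
}

test_that("suppression rho hits +1 / -1 on perfectly (anti)aligned ranks", {
    ranked <- data.frame(rank = 1:10, gene = sprintf("g%02d", 1:10),
                         similarity = seq(1, 0.1, length.out = 10))
    aligned <- fakeDE(sprintf("g%02d", 1:6), tstat = -(6:1))
    r1 <- suppressionRankCorrelation(ranked, aligned, "72h")
    expect_equal(r1$rho, 1)
    reversed <- fakeDE(sprintf("g%02d", 6:1), tstat = -(6:1))
    r2 <- suppressionRankCorrelation(ranked, reversed, "72h")
    expect_equal(r2$rho, -1)
    expect_error(suppressionRankCorrelation(ranked,
                                            aligned[1:2, ], "72h"),
                 "fewer than 3")
    ## genes missing from the ranked list are dropped with a warning
    odd <- fakeDE(c(sprintf("g%02d", 1:4), "zz"), tstat = -(5:1))
    expect_warning(r3 <- suppressionRankCorrelation(ranked, odd, "72h"),
                   "absent from")
    expect_identical(r3$n, 4L)
})

test_that("binomial over-representation matches brute-force summation", {
    N <- 1000L
    ranked <- data.frame(rank = seq_len(N),
                         gene = sprintf("g%04d", seq_len(N)),
                         similarity = seq(1, 0, length.out = N))
    ## 20 of the top-100 EMT genes among the 50 most down-regulated
    down <- c(sprintf("g%04d", 1:20), sprintf("g%04d", 501:530))
    de <- fakeDE(down, tstat = seq(-50, -1, length.out = 50))
    res <- overrepresentationBinomial(ranked, de, "72h", topKEmt = 100L,
                                      topMDown = 50L)
    expect_identical(res$overlap, 20L)
    expect_equal(res$pBinomial, bruteBinomTail(20, 50, 0.1),
                 tolerance = 1e-12)

    ## zero overlap is certain
    de0 <- fakeDE(sprintf("g%04d", 901:950),
                  tstat = seq(-50, -1, length.out = 50))
    expect_equal(overrepresentationBinomial(ranked, de0, "72h",
                                            topKEmt = 100L,
                                            topMDown = 50L)$pBinomial, 1)

    ## tail strictly decreases in the overlap
    ps <- vapply(c(5, 10, 15, 20), function(x) {
        dex <- fakeDE(c(sprintf("g%04d", seq_len(x)),
                        sprintf("g%04d", 500 + seq_len(50 - x))),
                      tstat = seq(-50, -1, length.out = 50))
        overrepresentationBinomial(ranked, dex, "72h", topKEmt = 100L,
                                   topMDown = 50L)$pBinomial
    }, numeric(1))
    expect_true(all(diff(ps) < 0))
    expect_error(overrepresentationBinomial(ranked, de[0, ], "72h"),
                 "empty down-regulated")
})
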