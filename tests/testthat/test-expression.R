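makeRE <- function(ex, dp = NULL, group = NULL, replicate = NULL) {
    if (is.null(dp)) dp <- matrix(0.001, nrow(ex), ncol(ex),
                                  dimnames = dimnames(ex))
    if (is.null(group)) group <- rep(c("donor", "24h"),
                                     each = ncol(ex) / 2)
    if (is.null(replicate)) replicate <- rep(c("a", "b"), ncol(ex) / 2)
    ReprogExperiment(ex, dp, group, replicate)
}

test_that("quantile normalization matches the hand-computed oracle", {
    raw <- cbind(s1 = c(1, 2, 3), s2 = c(4, 6, 8))
    rownames(raw) <- paste0("P", 1:3)
    qn <- quantileNormalize(raw)
    expect_equal(unname(qn[, 1]), c(2.5, 4, 5.5))
    expect_equal(unname(qn[, 2]), c(2.5, 4, 5.5))

    ## rank order preserved under permutation of rows
    raw2 <- raw[c(3, 1, 2), ]
    qn2 <- quantileNormalize(raw2)
    expect_equal(unname(qn2[, 2]), c(5.5, 2.5, 4))

    ## idempotence and the single-column identity
    expect_equal(quantileNormalize(qn), qn)
    one <- raw[, 1, drop = FALSE]
    expect_identical(quantileNormalize(one), one)
})

test_that("normalizeExpression rejects non-positive intensities by name", {
    raw <- matrix(c(2, 4, 0, 8), 2, 2,
                  dimnames = list(c("PA", "PB"), c("s1", "s2")))
    dp <- matrix(0.5, 2, 2, dimnames = dimnames(raw))
    expect_error(normalizeExpression(raw, dp, c("donor", "donor"),
                                     c("a", "b")),
                 "probe 'PA', sample 's2'")
})

test_that("detection calls use the strict 0.01 threshold", {
    dp <- matrix(c(0.009, 0.010, 0.0099999, 0.02), 2, 2,
                 dimnames = list(c("P1", "P2"), c("s1", "s2")))
    ex <- matrix(8, 2, 2, dimnames = dimnames(dp))
    re <- ReprogExperiment(ex, dp, group = c("donor", "donor"),
                           replicate = c("a", "b"))
    calls <- callDetection(re)
    expect_identical(unname(presentCalls(calls)),
                     matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2))
})

test_that("duplicate-present filter keeps probes present in both replicates
           of some group", {
    ## P1 present in both donor reps; P2 in one donor rep only; P3 present
    ## in both iPS reps; P4 nowhere
    dp <- rbind(P1 = c(0.001, 0.002, 0.5, 0.6),
                P2 = c(0.001, 0.500, 0.5, 0.6),
                P3 = c(0.800, 0.900, 1e-4, 1e-4),
                P4 = c(0.500, 0.500, 0.5, 0.5))
    colnames(dp) <- c("d-a", "d-b", "i-a", "i-b")
    ex <- matrix(8, 4, 4, dimnames = dimnames(dp))
    re <- ReprogExperiment(ex, dp, group = c("donor", "donor", "iPS",
                                             "iPS"),
                           replicate = c("a", "b", "a", "b"))
    expect_setequal(analysisSet(callDetection(re)), c("P1", "P3"))

    ## single-replicate group degenerates with a warning
    re1 <- ReprogExperiment(ex[, 1:3], dp[, 1:3],
                            group = c("donor", "donor", "iPS"),
                            replicate = c("a", "b", "a"))
    expect_warning(c1 <- callDetection(re1), "single replicate")
    expect_true("P3" %in% analysisSet(c1))
})

test_that("ordinary t (priorDf = 0) matches the pooled-t formula", {
    ex <- rbind(PX = c(5.0, 5.2, 7.1, 6.9),
                PY = c(6.0, 6.4, 6.1, 6.3))
    colnames(ex) <- c("d-a", "d-b", "c-a", "c-b")
    re <- makeRE(ex, group = c("donor", "donor", "24h", "24h"))
    calls <- callDetection(re)
    de <- differentialExpression(re, calls, "24h", priorDf = 0)
    px <- de[de$probe == "PX", ]
    ## hand-derived: means 5.1 / 7.0, pooled var 0.02, se = sqrt(0.02)
    expect_equal(px$logFC, 1.9, tolerance = 1e-12)
    expect_equal(px$t, 1.9 / sqrt(0.02), tolerance = 1e-9)
    expect_equal(px$t, 13.43502884, tolerance = 1e-7)
    expect_identical(px$df, 2)
    expect_equal(px$pValue, 2 * pt(-abs(px$t), 2), tolerance = 1e-12)
})

test_that("null contrasts give zero logFC and no regulation", {
    ex <- matrix(rep(c(5, 6, 7, 8), each = 4), 4, 4, byrow = TRUE,
                 dimnames = list(paste0("P", 1:4), paste0("s", 1:4)))
    re <- makeRE(ex, group = c("donor", "donor", "24h", "24h"))
    calls <- callDetection(re)
    expect_warning(de <- differentialExpression(re, calls, "24h",
                                                priorDf = 0),
                   "zero-variance")
    expect_true(all(de$logFC == 0))
    expect_true(all(!de$regulated))
})

test_that("regulated flag respects both thresholds", {
    sim <- smallSimulation(seed = 11L)
    calls <- callDetection(sim$experiment)
    de <- differentialExpressionAll(sim$experiment, calls)
    expect_true(all(de$regulated ==
        (!is.na(de$adjPValue) & de$adjPValue < 0.05 &
             abs(de$logFC) > log2(1.5))))
    expect_true(all(de$direction[de$regulated & de$logFC > 0] == "up"))
    expect_true(all(de$direction[de$regulated & de$logFC < 0] == "down"))
    expect_true(all(de$direction[!de$regulated] == "none"))
})

test_that("moderated t agrees with the limma cross-check on ranking", {
    sim <- smallSimulation(seed = 13L, nProbes = 500L)
    re <- sim$experiment
    calls <- callDetection(re)
    de <- differentialExpression(re, calls, "72h")
    grp <- sampleGroups(re)
    keep <- grp %in% c("donor", "72h")
    x <- intensities(re)[analysisSet(calls), keep]
    design <- cbind(1, as.integer(grp[keep] == "72h"))
    fit <- limma::eBayes(limma::lmFit(x, design))
    expect_equal(unname(fit$coefficients[, 2]), de$logFC,
                 tolerance = 1e-8)
    expect_gt(cor(fit$t[, 2], de$t), 0.995)
})

test_that("BH adjustment matches hand example and is monotone", {
    expect_equal(adjustBH(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_identical(adjustBH(0.3), 0.3)
    set.seed(1)
    p <- runif(40)
    a <- adjustBH(p)
    expect_true(all(a >= p - 1e-15))
    expect_true(all(a <= 1))
    expect_true(all(diff(a[order(p)]) >= -1e-12))
    expect_error(adjustBH(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("regulation profiles encode the five contrasts in order", {
    de <- expand.grid(probe = c("PA", "PB"),
                      contrast = c("24h", "48h", "72h", "iPS", "ES"),
                      stringsAsFactors = FALSE)
    de$regulated <- FALSE
    de$regulated[de$probe == "PA" & de$contrast != "24h"] <- TRUE
    prof <- regulationProfile(de)
    expect_identical(prof$profile[prof$probe == "PA"], "01111")
    expect_identical(prof$profile[prof$probe == "PB"], "00000")
    expect_error(regulationProfile(de[de$contrast != "iPS", ]),
                 "missing contrast")
    ## at most 2^5 distinct profiles on any dataset
    sim <- smallSimulation(seed = 17L, nProbes = 400L)
    calls <- callDetection(sim$experiment)
    deAll <- differentialExpressionAll(sim$experiment, calls)
    expect_lte(length(unique(regulationProfile(deAll)$profile)), 32L)
})

test_that("PCA projection matches the eigen oracle on toy data", {
    ## 2 probes, known covariance: first axis along the dominant direction
    set.seed(2)
    z <- matrix(rnorm(2 * 200), 2, 200)
    x <- rbind(z[1, ] * 3, z[1, ] * 3 * 0.5 + z[2, ] * 0.5)
    rownames(x) <- c("P1", "P2")
    colnames(x) <- paste0("s", 1:200)
    pc <- pcaProjection(x)
    ev <- eigen(cov(t(x - rowMeans(x))))$vectors[, 1]
    proj <- as.vector(t(x - rowMeans(x)) %*% ev)
    expect_gt(abs(cor(pc$PC1, proj)), 1 - 1e-10)
    ve <- attr(pc, "varianceExplained")
    expect_true(all(diff(ve) <= 1e-12))

    ## duplicate samples coincide
    y <- matrix(c(1, 2, 1, 2, 5, 9), 2, 3,
                dimnames = list(c("P1", "P2"), c("a", "b", "c")))
    pcy <- pcaProjection(y)
    expect_equal(pcy[pcy$sample == "a", c("PC1", "PC2")],
                 pcy[pcy$sample == "b", c("PC1", "PC2")],
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_error(pcaProjection(y[, 1:2]), "3 samples")
})
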