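## four pluripotent samples (iPS a/b, ES a/b) + two donor replicates
pluriExperiment <- function() {
    dp <- rbind(
        DNMT3B = c(0.5, 0.6, 1e-3, 1e-3, 1e-3, 1e-3),  # pluri-associated
        CD59   = c(1e-3, 1e-3, 0.5, 0.6, 0.7, 0.8),    # fibro-associated
        GAPDH  = c(1e-3, 1e-3, 1e-3, 1e-3, 1e-3, 1e-3),# everywhere
        HALF   = c(0.5, 0.6, 1e-3, 0.5, 1e-3, 1e-3))   # one iPS rep only
    colnames(dp) <- c("d-a", "d-b", "i-a", "i-b", "e-a", "e-b")
    ex <- matrix(8, nrow(dp), ncol(dp), dimnames = dimnames(dp))
    ReprogExperiment(ex, dp, group = c("donor", "donor", "iPS", "iPS",
                                       "ES", "ES"),
                     replicate = rep(c("a", "b"), 3))
}

test_that("associated sets follow the presence/absence definitions", {
    re <- pluriExperiment()
    calls <- callDetection(re)
    part <- deriveAssociatedSets(calls, sampleGroups(re))
    expect_identical(part$pluripotencyAssociated, "DNMT3B")
    expect_identical(part$fibroblastAssociated, "CD59")
    ## present everywhere -> neither; partial pluripotent presence -> out
    expect_false("GAPDH" %in% unlist(part))
    expect_false("HALF" %in% unlist(part))
    expect_length(intersect(part$pluripotencyAssociated,
                            part$fibroblastAssociated), 0)

    ## relaxed mode admits group-level presence in one pluripotent group
    part2 <- deriveAssociatedSets(calls, sampleGroups(re), mode = "any")
    expect_true("DNMT3B" %in% part2$pluripotencyAssociated)

    expect_error(deriveAssociatedSets(calls, rep("donor", 6)),
                 "missing required group")
})

test_that("partition is always disjoint and inside the analysis set", {
    for (s in 1:5) {
        sim <- smallSimulation(seed = s, nProbes = 300L)
        calls <- callDetection(sim$experiment)
        part <- deriveAssociatedSets(calls, sampleGroups(sim$experiment))
        expect_length(intersect(part$pluripotencyAssociated,
                                part$fibroblastAssociated), 0)
        expect_true(all(unlist(part) %in% analysisSet(calls)))
    }
})

test_that("activation time course recovers planted fractions exactly at
           zero noise", {
    sim <- smallSimulation(seed = 21L, noiseSd = 0)
    calls <- callDetection(sim$experiment)
    grp <- sampleGroups(sim$experiment)
    part <- deriveAssociatedSets(calls, grp)
    expect_setequal(part$pluripotencyAssociated, sim$truth$pluriOn)
    expect_setequal(part$fibroblastAssociated, sim$truth$fibroOff)
    act <- activationTimecourse(calls, part, grp)
    expect_equal(act$pluripotencyFraction[act$group %in%
                                          c("24h", "48h", "72h")],
                 c(0.1, 0.2, 0.3))
    expect_equal(act$pluripotencyFraction[act$group == "donor"], 0)
    expect_equal(act$fibroblastFraction[act$group %in% c("iPS", "ES")],
                 c(0, 0))
})

test_that("activation arithmetic and empty-partition contract", {
    re <- pluriExperiment()
    calls <- callDetection(re)
    part <- list(pluripotencyAssociated = c("DNMT3B", "CD59", "GAPDH",
                                            "HALF"),
                 fibroblastAssociated = character())
    act <- activationTimecourse(calls, part, sampleGroups(re))
    ## 2 of 4 probes group-present in iPS -> 0.5
    expect_equal(act$pluripotencyFraction[act$group == "iPS"], 0.5)
    expect_warning(
        empty <- activationTimecourse(calls,
                                      list(pluripotencyAssociated =
                                               character(),
                                           fibroblastAssociated =
                                               character()),
                                      sampleGroups(re)),
        "empty")
    expect_identical(nrow(empty), 0L)
})

test_that("surface annotation subsets the pluripotency set", {
    part <- list(pluripotencyAssociated = c("PODXL", "DNMT3B"),
                 fibroblastAssociated = "CD59")
    ann <- list("cell surface" = c("PODXL", "CD59"),
                "integral to membrane" = "F11R")
    expect_identical(annotateSurface(part, ann), "PODXL")
    expect_warning(none <- annotateSurface(part, list(other = "X")),
                   "none of the requested terms")
    expect_length(none, 0)
    for (s in 1:3) {
        set.seed(s)
        genes <- sample(LETTERS, 10)
        part2 <- list(pluripotencyAssociated = genes[1:6])
        ann2 <- list("cell surface" = sample(LETTERS, 8))
        expect_true(all(annotateSurface(part2, ann2) %in% genes[1:6]))
    }
})

test_that("hypergeometric enrichment equals brute-force enumeration", {
    universe <- sprintf("g%02d", 1:20)
    ann <- list(T1 = universe[1:5], ALL = universe)
    res <- enrichHypergeometric(universe[1:5], universe, ann)
    ## complete overlap of a 5-gene term with a 5-gene query in 20:
    ## p = 1 / C(20,5) = 1/15504
    expect_equal(res$pValue[res$term == "T1"], 1 / 15504,
                 tolerance = 1e-12)
    expect_equal(res$pValue[res$term == "ALL"], 1)

    ## brute-force agreement on random small instances
    for (s in 1:25) {
        set.seed(s)
        N <- sample(8:25, 1)
        uni <- sprintf("u%02d", seq_len(N))
        K <- sample(1:N, 1)
        n <- sample(1:N, 1)
        annR <- list(T = sample(uni, K))
        q <- sample(uni, n)
        res <- enrichHypergeometric(q, uni, annR)
        x <- length(intersect(q, annR$T))
        expect_equal(res$pValue, bruteHyper(x, K, N, n), tolerance = 1e-10)
        expect_gt(res$pValue, 0)
        expect_lte(res$pValue, 1)
    }
    expect_error(enrichHypergeometric(c("zz"), universe, ann), "subset")
})

test_that("GMT round trip preserves sets", {
    sets <- list(A = c("x", "y", "z"), B = c("q"))
    f <- withr::local_tempfile(fileext = ".gmt")
    writeGMT(sets, f, description = c("da", "db"))
    back <- readGMT(f)
    expect_identical(back$A, sets$A)
    expect_identical(back$B, sets$B)
    expect_identical(attr(back, "description"), c("da", "db"))
    seed <- emtSeedGenes()
    expect_length(seed, 36)
    expect_true(all(c("SNAI1", "VIM", "TWIST1", "CDH2") %in% seed))
})
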