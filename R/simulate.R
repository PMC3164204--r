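## Seeded generators emulating the study design: duplicate donor fibroblasts,
## duplicate transduced samples at 24/48/72 h with progressively growing
## planted effects, and duplicate iPS-like / ES-like pluripotent references.
## Every planting is recorded in a ground-truth object so downstream stages
## can be tested by recovery.

withSeed <- function(seed, code) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
    force(code)
}

#' Specification of a synthetic reprogramming time-course experiment
#'
#' Bundles and validates the parameters of \code{\link{simulateExpression}}.
#' Defaults emulate the study design: two donor fibroblast replicates,
#' duplicates at 24/48/72 h post-transduction, and two iPS-like plus two
#' ES-like pluripotent samples.
#'
#' @param nProbes number of probes on the simulated array (default 24526,
#'   the probe count of the emulated bead chip after preprocessing).
#' @param groups named integer vector: replicates per ordered group.
#' @param donorGroup,timeGroups,pluriGroups group labels giving each group
#'   its role; \code{timeGroups} must be ordered early to late.
#' @param deFraction fraction of probes planted as differential per contrast.
#' @param effectLog2FC planted |log2 fold change| at the first time point.
#' @param effectGrowth multiplier applied per successive time point; the
#'   pluripotent groups carry one further step (the matured effect).
#' @param noiseSd per-observation Gaussian noise sd on the log2 scale.
#'   The duplicate-to-duplicate spread is a free parameter of the generator
#'   (0.25 by default), not a reported quantity.
#' @param pluriOnGenes,fibroOffGenes numbers of probes planted to switch
#'   detection state (off->on towards pluripotency, and the mirror image).
#' @param activationFractions per-time-point fraction of \code{pluriOnGenes}
#'   already detectable (non-decreasing); the same fractions drive the
#'   progressive extinction of \code{fibroOffGenes}.
#' @param emtSeedGenes probe ids planted for progressive down-regulation
#'   (the synthetic EMT module); magnitudes taper linearly from
#'   \code{emtEffectRange[1]} to \code{emtEffectRange[2]} along the list.
#' @param emtEffectRange length-2 numeric, strongest and weakest planted
#'   EMT |log2FC| at the first time point.
#' @param emtEffectGrowth per-step multiplier for the planted EMT module
#'   (default 2): EMT suppression deepens faster than the generic
#'   response, so the module progressively overtakes the background
#'   down-regulated genes — the mechanism behind the rising suppression
#'   signature.
#' @param lineOffsetSd sd of a per-sample baseline offset within the
#'   pluripotent groups (distinct lines treated as replicates; 0 = off).
#' @param rngSeed integer seed; identical specs give identical output.
#' @return A validated list of class \code{"SyntheticExpressionSpec"}.
#' @export
syntheticExpressionSpec <- function(nProbes = 24526,
                                    groups = c(donor = 2L, "24h" = 2L,
                                               "48h" = 2L, "72h" = 2L,
                                               iPS = 2L, ES = 2L),
                                    donorGroup = "donor",
                                    timeGroups = c("24h", "48h", "72h"),
                                    pluriGroups = c("iPS", "ES"),
                                    deFraction = 0.05,
                                    effectLog2FC = 1,
                                    effectGrowth = 1.5,
                                    noiseSd = 0.25,
                                    pluriOnGenes = 200L,
                                    fibroOffGenes = 150L,
                                    activationFractions = c(0.1, 0.2, 0.3),
                                    emtSeedGenes = character(),
                                    emtEffectRange = c(3.5, 1),
                                    emtEffectGrowth = 1.8,
                                    lineOffsetSd = 0,
                                    rngSeed = 1L) {
    spec <- list(nProbes = as.integer(nProbes), groups = groups,
                 donorGroup = donorGroup, timeGroups = timeGroups,
                 pluriGroups = pluriGroups, deFraction = deFraction,
                 effectLog2FC = effectLog2FC, effectGrowth = effectGrowth,
                 noiseSd = noiseSd, pluriOnGenes = as.integer(pluriOnGenes),
                 fibroOffGenes = as.integer(fibroOffGenes),
                 activationFractions = activationFractions,
                 emtSeedGenes = as.character(emtSeedGenes),
                 emtEffectRange = emtEffectRange,
                 emtEffectGrowth = emtEffectGrowth,
                 lineOffsetSd = lineOffsetSd, rngSeed = as.integer(rngSeed))
    class(spec) <- "SyntheticExpressionSpec"
    validateExpressionSpec(spec)
    spec
}

validateExpressionSpec <- function(spec) {
    if (spec$nProbes <= 0L)
        stop("nProbes must be positive")
    if (length(spec$groups) == 0L || any(spec$groups < 1L))
        stop("groups must be non-empty with at least one replicate each")
    roles <- c(spec$donorGroup, spec$timeGroups, spec$pluriGroups)
    unknown <- setdiff(roles, names(spec$groups))
    if (length(unknown))
        stop("unknown group label(s): ", paste(unknown, collapse = ", "))
    if (spec$deFraction < 0 || spec$deFraction > 1)
        stop("deFraction must lie in [0, 1]")
    af <- spec$activationFractions
    if (length(af) != length(spec$timeGroups))
        stop("activationFractions must give one value per time group")
    if (any(af < 0) || any(af > 1) || is.unsorted(af))
        stop("activationFractions must be non-decreasing values in [0, 1]")
    if (spec$pluriOnGenes < 0L || spec$fibroOffGenes < 0L)
        stop("planted set sizes must be non-negative")
    if (spec$noiseSd < 0)
        stop("noiseSd must be non-negative")
    invisible(TRUE)
}

#' Simulate a reprogramming time-course expression experiment
#'
#' Draws a probe x sample log2 intensity matrix with coupled detection
#' p-values from a \code{\link{syntheticExpressionSpec}}. Planted
#' differential probes differ from the donor mean by
#' \code{effectLog2FC * effectGrowth^k} (k = 0, 1, 2 at 24/48/72 h; k = 3 in
#' the pluripotent groups). Detection p-values are drawn Uniform(0, 0.009]
#' for expressed states and Uniform(0.02, 1) otherwise, so the 0.01 call
#' threshold separates them exactly. Unexpressed states sit at a background
#' intensity of 4 on the log2 scale.
#'
#' @param spec a \code{\link{syntheticExpressionSpec}}.
#' @return list with elements \code{experiment}
#'   (\linkS4class{ReprogExperiment}) and \code{truth} (planted DE status
#'   and expected log2FC per contrast, planted detection states per group,
#'   and the planted probe sets).
#' @export
simulateExpression <- function(spec) {
    stopifnot(inherits(spec, "SyntheticExpressionSpec"))
    validateExpressionSpec(spec)
    n <- spec$nProbes
    probes <- sprintf("P%05d", seq_len(n))
    emt <- spec$emtSeedGenes
    if (length(emt) && !all(emt %in% probes))
        stop("emtSeedGenes must be probe ids of the simulated array")

    groupOf <- rep(names(spec$groups), times = spec$groups)
    repOf <- unlist(lapply(spec$groups, function(k) letters[seq_len(k)]),
                    use.names = FALSE)
    samples <- paste(groupOf, repOf, sep = "-")
    ## effect steps: 0, 1, 2 across the time course; the pluripotent groups
    ## continue the progression (iPS, then ES as the fully established
    ## pluripotent state)
    contrasts <- c(spec$timeGroups, spec$pluriGroups)
    stepOf <- setNames(c(seq_along(spec$timeGroups) - 1L,
                         length(spec$timeGroups) - 1L +
                             seq_along(spec$pluriGroups)), contrasts)

    withSeed(spec$rngSeed, {
        mu <- runif(n, 6, 12)

        ## disjoint planted pools: EMT seeds first, then detection-state
        ## probes, then background DE probes
        avail <- setdiff(probes, emt)
        nDE <- round(spec$deFraction * n)
        pluriOn <- utils::head(avail, spec$pluriOnGenes)
        avail <- setdiff(avail, pluriOn)
        fibroOff <- utils::head(avail, spec$fibroOffGenes)
        avail <- setdiff(avail, fibroOff)
        if (nDE > length(avail))
            stop("deFraction too large for the available probe pool")
        dePlanted <- sample(avail, nDE)
        deUp <- dePlanted[seq_len(ceiling(nDE / 2))]
        deDown <- setdiff(dePlanted, deUp)

        ## expected log2FC per probe x contrast
        delta <- matrix(0, n, length(contrasts),
                        dimnames = list(probes, contrasts))
        for (ct in contrasts) {
            eff <- spec$effectLog2FC * spec$effectGrowth^stepOf[[ct]]
            delta[deUp, ct] <- eff
            delta[deDown, ct] <- -eff
            if (length(emt)) {
                base <- seq(spec$emtEffectRange[1], spec$emtEffectRange[2],
                            length.out = length(emt))
                delta[emt, ct] <- -base * spec$emtEffectGrowth^stepOf[[ct]]
            }
        }

        ## detection states: expressed TRUE/FALSE per probe x group
        groupsAll <- names(spec$groups)
        expressed <- matrix(TRUE, n, length(groupsAll),
                            dimnames = list(probes, groupsAll))
        offGroups <- c(spec$donorGroup, spec$timeGroups)
        expressed[pluriOn, offGroups] <- FALSE
        expressed[fibroOff, spec$pluriGroups] <- FALSE
        for (k in seq_along(spec$timeGroups)) {
            tg <- spec$timeGroups[k]
            mOn <- round(spec$activationFractions[k] * length(pluriOn))
            if (mOn > 0) expressed[pluriOn[seq_len(mOn)], tg] <- TRUE
            mOff <- round(spec$activationFractions[k] * length(fibroOff))
            if (mOff > 0) expressed[fibroOff[seq_len(mOff)], tg] <- FALSE
        }

        ## means: background 4 when unexpressed, mu + planted shift otherwise
        deltaFull <- cbind(delta,
                           matrix(0, n, 1,
                                  dimnames = list(probes, spec$donorGroup)))
        mean.mat <- matrix(0, n, length(samples),
                           dimnames = list(probes, samples))
        for (j in seq_along(samples)) {
            g <- groupOf[j]
            m <- mu + deltaFull[, g]
            m[!expressed[, g]] <- 4
            mean.mat[, j] <- m
        }
        if (spec$lineOffsetSd > 0) {
            pl <- groupOf %in% spec$pluriGroups
            off <- rnorm(sum(pl), 0, spec$lineOffsetSd)
            mean.mat[, pl] <- sweep(mean.mat[, pl, drop = FALSE], 2, off, "+")
        }
        ex <- mean.mat + matrix(rnorm(n * length(samples), 0, spec$noiseSd),
                                n, length(samples))
        exprState <- expressed[, groupOf, drop = FALSE]
        dp <- matrix(runif(n * length(samples), 0.02, 1), n, length(samples))
        dp[exprState] <- runif(sum(exprState), 0, 0.009)
        dimnames(ex) <- dimnames(dp) <- list(probes, samples)

        deStatus <- matrix("null", n, length(contrasts),
                           dimnames = list(probes, contrasts))
        deStatus[deUp, ] <- "up"
        deStatus[deDown, ] <- "down"
        if (length(emt)) deStatus[emt, ] <- "down"

        truth <- list(deStatus = deStatus, expectedLog2FC = delta,
                      detectionState = expressed, deUp = deUp,
                      deDown = deDown, pluriOn = pluriOn,
                      fibroOff = fibroOff, emtSeeds = emt)
        list(experiment = ReprogExperiment(ex, dp, group = groupOf,
                                           replicate = repOf),
             truth = truth)
    })
}

#' Simulate a co-expression compendium with a planted seed module
#'
#' Genes inside \code{seedModule} load on one shared latent factor so that
#' every within-module pair has expected Pearson correlation
#' \code{moduleCorrelation}; all other genes are independent standard
#' normals. Surrogate for the expression compendium behind seed-based
#' genome ranking.
#'
#' @param nGenes,nSamples table dimensions (\code{nSamples >= 3}).
#' @param seedModule character ids of the co-expressed module; ids not of
#'   the form \code{G#####} are added to the gene universe.
#' @param moduleCorrelation target pairwise correlation in [0, 1].
#' @param moduleLoadings optional per-module-gene factor loadings in
#'   [0, 1] (one per \code{seedModule} entry, in order), overriding the
#'   homogeneous \code{sqrt(moduleCorrelation)}; a pair of module genes
#'   then has expected correlation \code{loading_i * loading_j}. Use a
#'   tapered vector to grade how EMT-like each module gene is.
#' @param rngSeed integer seed.
#' @return numeric matrix, genes x samples, with gene ids as rownames.
#' @export
simulateCompendium <- function(nGenes, nSamples, seedModule = character(),
                               moduleCorrelation = 0.9,
                               moduleLoadings = NULL, rngSeed = 1L) {
    if (moduleCorrelation < 0 || moduleCorrelation > 1)
        stop("moduleCorrelation must lie in [0, 1]")
    if (nSamples < 3)
        stop("at least 3 samples required")
    seedModule <- as.character(seedModule)
    filler <- sprintf("G%05d", seq_len(nGenes))
    genes <- unique(c(seedModule, filler))[seq_len(max(nGenes,
                                                       length(seedModule)))]
    if (!all(seedModule %in% genes))
        stop("seedModule must fit inside the gene universe")
    withSeed(rngSeed, {
        x <- matrix(rnorm(length(genes) * nSamples), length(genes), nSamples,
                    dimnames = list(genes, sprintf("S%03d",
                                                   seq_len(nSamples))))
        if (length(seedModule) && (moduleCorrelation > 0 ||
                                   !is.null(moduleLoadings))) {
            lam <- if (is.null(moduleLoadings))
                rep(sqrt(moduleCorrelation), length(seedModule))
            else moduleLoadings
            if (length(lam) != length(seedModule) ||
                any(lam < 0) || any(lam > 1))
                stop("moduleLoadings must give one value in [0, 1] per ",
                     "module gene")
            f <- rnorm(nSamples)
            x[seedModule, ] <- lam * matrix(f, length(seedModule), nSamples,
                                            byrow = TRUE) +
                sqrt(1 - lam^2) * x[seedModule, , drop = FALSE]
        }
        x
    })
}

#' Simulate an interaction network with planted source-to-sink paths
#'
#' Builds a mixed graph whose planted paths are guaranteed shortest: each
#' planted path's edges are laid down (the first hop from a source as a
#' regulatory edge, subsequent hops as undirected ppi edges), then random
#' background ppi edges are added at \code{edgeProb} — skipping, unless
#' \code{allowShortcuts}, any edge that would shorten a planted pair's
#' distance below its planted length.
#'
#' @param nNodes number of background nodes (\code{N1 ... NnNodes}); nodes
#'   named in \code{sources}, \code{sinks} or \code{plantedPaths} are added
#'   to the universe.
#' @param edgeProb background edge probability in [0, 1].
#' @param sources,sinks disjoint node id vectors.
#' @param plantedPaths list of node-id sequences; each must start at a
#'   declared source and end at a declared sink.
#' @param rngSeed integer seed.
#' @param allowShortcuts keep background edges even when they shorten a
#'   planted path (default FALSE).
#' @return An \linkS4class{InteractionNetwork}.
#' @export
simulateNetwork <- function(nNodes, edgeProb, sources, sinks,
                            plantedPaths = list(), rngSeed = 1L,
                            allowShortcuts = FALSE) {
    if (edgeProb < 0 || edgeProb > 1)
        stop("edgeProb must lie in [0, 1]")
    if (length(intersect(sources, sinks)))
        stop("sources and sinks must be disjoint")
    for (p in plantedPaths) {
        if (length(p) < 2L)
            stop("planted paths need at least two nodes")
        if (!(p[1] %in% sources) || !(p[length(p)] %in% sinks))
            stop("planted path endpoints must be declared sources/sinks: ",
                 paste(p, collapse = "->"))
    }
    nodes <- unique(c(sprintf("N%02d", seq_len(nNodes)), sources, sinks,
                      unlist(plantedPaths)))
    edges <- data.frame(from = character(), type = character(),
                        to = character(), stringsAsFactors = FALSE)
    addEdge <- function(e, a, ty, b) {
        dup <- (e$from == a & e$to == b) |
            (e$type == "ppi" & ty == "ppi" & e$from == b & e$to == a)
        if (any(dup)) e else rbind(e, data.frame(from = a, type = ty, to = b))
    }
    for (p in plantedPaths)
        for (i in seq_len(length(p) - 1L))
            edges <- addEdge(edges, p[i],
                             if (i == 1L) "reg" else "ppi", p[i + 1L])
    plantedLen <- lapply(plantedPaths, function(p)
        list(from = p[1], to = p[length(p)], len = length(p) - 1L))

    withSeed(rngSeed, {
        cand <- which(upper.tri(matrix(0, length(nodes), length(nodes))),
                      arr.ind = TRUE)
        keep <- runif(nrow(cand)) < edgeProb
        for (r in which(keep)) {
            a <- nodes[cand[r, 1]]; b <- nodes[cand[r, 2]]
            if (a == b) next
            trial <- addEdge(edges, a, "ppi", b)
            if (nrow(trial) == nrow(edges)) next
            if (!allowShortcuts && length(plantedLen)) {
                netTrial <- InteractionNetwork(trial, sources, sinks,
                                               nodes = nodes)
                short <- any(vapply(plantedLen, function(pp)
                    mixedDistance(netTrial, pp$from, pp$to) < pp$len,
                    logical(1)))
                if (short) next
            }
            edges <- trial
        }
        InteractionNetwork(edges, sources, sinks, nodes = nodes)
    })
}
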