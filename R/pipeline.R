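## End-to-end orchestration from a single configuration: normalize ->
## detection calls -> differential expression (five contrasts) ->
## regulation profiles -> gene-set dynamics -> fuzzy clustering -> EMT
## signature -> network scoring, with one TSV per stage and a JSON
## manifest. Identical config + seed give byte-identical outputs.

#' Default pipeline configuration
#'
#' All thresholds of the analysis live here with the study's values as
#' defaults (detection 0.01, adjusted p 0.05, fold change 1.5, fuzzifier
#' 1.7 with nine clusters, alpha-core 0.5, ten recovery bins, 0.75 high
#' quantile), so a re-analysis is a configuration change, not a code
#' change. Exactly one of \code{synthetic} (generator parameters) or
#' \code{input} (paths to an expression TSV + sample table) must be set.
#'
#' @param rngSeed integer master seed.
#' @param outDir output directory.
#' @return nested configuration list.
#' @export
defaultRunConfig <- function(rngSeed = 1L, outDir = "reprog-run") {
    list(
        rngSeed = as.integer(rngSeed),
        outDir = outDir,
        synthetic = list(nProbes = 24526L, deFraction = 0.05,
                         effectLog2FC = 1, effectGrowth = 1.5,
                         noiseSd = 0.25, pluriOnGenes = 200L,
                         fibroOffGenes = 150L,
                         activationFractions = c(0.1, 0.2, 0.3),
                         emtSeedGenes = sprintf("P%05d", 1:36)),
        input = NULL,
        thresholds = list(detection = 0.01, pAdj = 0.05, foldChange = 1.5,
                          fuzzifier = 1.7, clusterCount = 9L,
                          alphaCore = 0.5, nBins = 10L,
                          highQuantile = 0.75),
        compendium = list(nSamples = 60L, moduleCorrelation = 0.8,
                          loadingRange = c(0.95, 0.5)),
        emt = list(leaveOutFraction = 0.1, nRepeats = 20L, topKEmt = 100L),
        network = list(sif = NULL, roles = NULL, via = "GSK3B",
                       undirectedAll = FALSE),
        contrasts = c("24h", "48h", "72h", "iPS", "ES"),
        donorGroup = "donor")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Values present in the file override the defaults of
#' \code{\link{defaultRunConfig}}.
#'
#' @param path config file (\code{.yaml}/\code{.yml} or \code{.json}).
#' @return configuration list.
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path)) stop("missing config file: ", path)
    user <- if (grepl("\\.json$", path)) jsonlite::read_json(
        path, simplifyVector = TRUE) else yaml::read_yaml(path)
    mergeConfig(defaultRunConfig(), user)
}

mergeConfig <- function(base, user) {
    for (nm in names(user)) {
        if (is.list(user[[nm]]) && is.list(base[[nm]]))
            base[[nm]] <- mergeConfig(base[[nm]], user[[nm]])
        else base[[nm]] <- user[[nm]]
    }
    base
}

validateRunConfig <- function(config) {
    th <- config$thresholds
    inRange <- function(v, lo, hi) is.numeric(v) && v > lo && v <= hi
    if (!inRange(th$detection, 0, 1))
        stop("detection threshold must lie in (0, 1]")
    if (!inRange(th$pAdj, 0, 1))
        stop("adjusted-p threshold must lie in (0, 1]")
    if (th$foldChange <= 1) stop("fold-change threshold must exceed 1")
    if (th$fuzzifier <= 1) stop("fuzzifier must exceed 1")
    if (th$alphaCore < 0 || th$alphaCore > 1)
        stop("alpha-core threshold must lie in [0, 1]")
    if (th$nBins < 2) stop("nBins must be at least 2")
    if (th$highQuantile < 0 || th$highQuantile > 1)
        stop("highQuantile must lie in [0, 1]")
    hasSyn <- !is.null(config$synthetic)
    hasInp <- !is.null(config$input)
    if (hasSyn == hasInp)
        stop("exactly one of 'synthetic' or 'input' must be set")
    if (hasInp) {
        for (f in unlist(config$input))
            if (!file.exists(f)) stop("missing input file: ", f)
    }
    invisible(TRUE)
}

writeStage <- function(tab, outDir, name) {
    path <- file.path(outDir, name)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
}

#' Run the full analysis pipeline
#'
#' Executes every stage from one configuration and writes one TSV per
#' stage plus \code{manifest.json} (configuration echo, package version,
#' seed, and per-stage row counts — no timestamps, so reruns with the same
#' configuration and seed are byte-identical).
#'
#' @param config configuration list (\code{\link{defaultRunConfig}} or
#'   \code{\link{readRunConfig}}).
#' @return invisibly, a list with the in-memory stage results.
#' @export
runPipeline <- function(config = defaultRunConfig()) {
    validateRunConfig(config)
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    th <- config$thresholds
    counts <- list()
    stage <- function(name, code) {
        message("[", name, "] ...")
        tryCatch(code, error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }

    truth <- NULL
    re <- stage("input", {
        if (!is.null(config$synthetic)) {
            spec <- do.call(syntheticExpressionSpec,
                            c(config$synthetic,
                              list(rngSeed = config$rngSeed)))
            sim <- simulateExpression(spec)
            truth <- sim$truth
            sim$experiment
        } else {
            readExpressionTSV(config$input$exprFile,
                              config$input$sampleFile)
        }
    })
    counts$probes <- nrow(re)
    counts$samples <- ncol(re)

    calls <- stage("detection", callDetection(re, th$detection))
    counts$analysisSet <- length(analysisSet(calls))
    message("  analysis set: ", counts$analysisSet, " / ", nrow(re),
            " probes")

    de <- stage("differential-expression",
                differentialExpressionAll(re, calls,
                                          contrasts = config$contrasts,
                                          donorGroup = config$donorGroup,
                                          pAdjThreshold = th$pAdj,
                                          fcThreshold = th$foldChange))
    prof <- regulationProfile(de, config$contrasts)
    counts$regulated <- vapply(config$contrasts, function(ct)
        sum(de$regulated[de$contrast == ct]), integer(1))
    deWide <- prof
    for (ct in config$contrasts) {
        d <- de[de$contrast == ct, ]
        m <- match(deWide$probe, d$probe)
        deWide[[paste0("logFC.", ct)]] <- d$logFC[m]
        deWide[[paste0("adjP.", ct)]] <- d$adjPValue[m]
    }
    writeStage(deWide, config$outDir, "de_results.tsv")

    pca <- stage("pca", pcaProjection(re))
    writeStage(pca, config$outDir, "pca_projection.tsv")

    grp <- sampleGroups(re)
    partition <- stage("gene-sets",
                       deriveAssociatedSets(calls, grp,
                                            donorGroup = config$donorGroup))
    counts$pluripotencyAssociated <-
        length(partition$pluripotencyAssociated)
    counts$fibroblastAssociated <- length(partition$fibroblastAssociated)
    writeStage(data.frame(
        probe = c(partition$pluripotencyAssociated,
                  partition$fibroblastAssociated),
        set = rep(c("pluripotency", "fibroblast"),
                  c(counts$pluripotencyAssociated,
                    counts$fibroblastAssociated))),
        config$outDir, "geneset_partition.tsv")
    act <- stage("activation",
                 activationTimecourse(calls, partition, grp))
    writeStage(act, config$outDir, "activation_timecourse.tsv")

    regProbes <- unique(de$probe[de$regulated])
    counts$clusteredProbes <- length(regProbes)
    clus <- stage("clustering", {
        if (length(regProbes) > th$clusterCount + 1L) {
            fcMat <- vapply(config$contrasts, function(ct) {
                d <- de[de$contrast == ct, ]
                d$logFC[match(regProbes, d$probe)]
            }, numeric(length(regProbes)))
            rownames(fcMat) <- regProbes
            fc <- fuzzyCMeans(standardizeProfiles(fcMat),
                              c = th$clusterCount, m = th$fuzzifier,
                              rngSeed = config$rngSeed)
            alphaCore(fc, th$alphaCore)
        } else NULL
    })
    if (!is.null(clus)) writeStage(clus, config$outDir, "clusters.tsv")

    emtRes <- stage("emt-signature", {
        seeds <- if (!is.null(truth) && length(truth$emtSeeds))
            truth$emtSeeds else emtSeedGenes()
        universe <- analysisSet(calls)
        seeds <- intersect(seeds, universe)
        if (length(seeds) >= 4L) {
            lr <- config$compendium$loadingRange
            loadings <- if (is.null(lr)) NULL else
                sqrt(seq(lr[1], lr[2], length.out = length(seeds)))
            comp <- simulateCompendium(
                nGenes = length(universe),
                nSamples = config$compendium$nSamples,
                seedModule = seeds,
                moduleCorrelation = config$compendium$moduleCorrelation,
                moduleLoadings = loadings,
                rngSeed = config$rngSeed + 1L)
            rownames(comp) <- c(seeds, setdiff(universe, seeds))
            ranked <- seedRank(comp, seeds)
            rec <- recoveryTest(comp, seeds,
                                leaveOutFraction =
                                    config$emt$leaveOutFraction,
                                nRepeats = config$emt$nRepeats,
                                nBins = th$nBins,
                                rngSeed = config$rngSeed + 2L)
            sig <- emtSignatureTable(ranked, de,
                                     contrasts = config$contrasts,
                                     topKEmt = config$emt$topKEmt)
            list(ranked = ranked, recovery = rec, signature = sig)
        } else NULL
    })
    if (!is.null(emtRes)) {
        writeStage(emtRes$ranked, config$outDir, "emt_ranked.tsv")
        writeStage(data.frame(bin = seq_along(emtRes$recovery$binCounts),
                              count = emtRes$recovery$binCounts),
                   config$outDir, "emt_recovery_bins.tsv")
        writeStage(emtRes$signature, config$outDir, "emt_signature.tsv")
        counts$recoveryP <- emtRes$recovery$pValue
    }

    netRes <- stage("network", {
        net <- if (!is.null(config$network$sif))
            readSIF(config$network$sif, config$network$roles)
        else reprogNetworkFixture()
        ua <- isTRUE(config$network$undirectedAll)
        sub <- buildSubnetwork(net, undirectedAll = ua)
        scores <- classifyNodes(scoreNodes(net, undirectedAll = ua),
                                th$highQuantile)
        via <- config$network$via
        paths <- if (!is.null(via) && via %in% networkNodes(net))
            pathsThrough(net, via = via, undirectedAll = ua) else list()
        list(network = net, subnetwork = sub, scores = scores,
             paths = paths)
    })
    counts$subnetworkNodes <- length(networkNodes(netRes$subnetwork))
    writeStage(netRes$scores, config$outDir, "network_scores.tsv")
    writeStage(data.frame(path = vapply(netRes$paths, paste,
                                        character(1), collapse = "->")),
               config$outDir, "network_paths.tsv")
    writeGraphML(netRes$subnetwork,
                 netRes$scores[netRes$scores$node %in%
                                   networkNodes(netRes$subnetwork), ],
                 file.path(config$outDir, "subnetwork.graphml"))

    manifest <- list(package = "earlyReprog",
                     version = as.character(utils::packageVersion(
                         "earlyReprog")),
                     rngSeed = config$rngSeed,
                     thresholds = th,
                     counts = counts)
    jsonlite::write_json(manifest,
                         file.path(config$outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    message("pipeline complete: ", config$outDir)
    invisible(list(experiment = re, truth = truth, calls = calls, de = de,
                   profiles = prof, pca = pca, partition = partition,
                   activation = act, clusters = clus, emt = emtRes,
                   network = netRes, manifest = manifest))
}
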