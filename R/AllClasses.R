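#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
NULL

#' ReprogExperiment: probe-level intensities with detection p-values
#'
#' Container for a bead-array style reprogramming time course: a probe x
#' sample matrix of log2-scale intensities together with a parallel matrix of
#' detection p-values (per-probe evidence that signal exceeds background),
#' and per-sample group/replicate annotation. Extends
#' \linkS4class{SummarizedExperiment} with assays \code{"exprs"} and
#' \code{"detectionP"}.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}
#' @export
setClass("ReprogExperiment", contains = "SummarizedExperiment")

setValidity("ReprogExperiment", function(object) {
    msg <- NULL
    an <- assayNames(object)
    if (!all(c("exprs", "detectionP") %in% an))
        msg <- c(msg, "assays must include 'exprs' and 'detectionP'")
    else {
        dp <- assay(object, "detectionP")
        if (anyNA(dp) || any(dp < 0) || any(dp > 1))
            msg <- c(msg, "detection p-values must lie in [0, 1]")
    }
    cd <- colData(object)
    if (!all(c("group", "replicate") %in% colnames(cd)))
        msg <- c(msg, "colData must carry 'group' and 'replicate'")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "probe identifiers (rownames) must be present and unique")
    if (is.null(msg)) TRUE else msg
})

#' Construct a ReprogExperiment
#'
#' @param exprs numeric matrix of log2 intensities, probes x samples, with
#'   unique rownames (probe ids) and colnames (sample ids).
#' @param detectionP numeric matrix of detection p-values, same dimensions.
#' @param group character/factor of sample group labels (one per column),
#'   e.g. \code{"donor"}, \code{"24h"}, \code{"48h"}, \code{"72h"},
#'   \code{"iPS"}, \code{"ES"}.
#' @param replicate replicate tags within group (one per column).
#' @return A \linkS4class{ReprogExperiment}.
#' @examples
#' ex <- matrix(rnorm(12, 8), 3, 4,
#'              dimnames = list(paste0("P", 1:3), paste0("S", 1:4)))
#' dp <- matrix(runif(12), 3, 4, dimnames = dimnames(ex))
#' ReprogExperiment(ex, dp, group = rep(c("donor", "iPS"), each = 2),
#'                  replicate = rep(c("a", "b"), 2))
#' @export
ReprogExperiment <- function(exprs, detectionP, group, replicate) {
    stopifnot(is.matrix(exprs), is.matrix(detectionP),
              all(dim(exprs) == dim(detectionP)))
    if (is.null(colnames(exprs)))
        colnames(exprs) <- colnames(detectionP) <-
            paste(group, replicate, sep = "-")
    se <- SummarizedExperiment(
        assays = list(exprs = exprs, detectionP = detectionP),
        colData = DataFrame(group = as.character(group),
                            replicate = as.character(replicate),
                            row.names = colnames(exprs)))
    new("ReprogExperiment", se)
}

#' @describeIn ReprogExperiment log2 intensity matrix
#' @param object,x a ReprogExperiment
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))
#' @export
setMethod("intensities", "ReprogExperiment",
          function(object) assay(object, "exprs"))

#' @describeIn ReprogExperiment detection p-value matrix
#' @export
setGeneric("detectionP", function(object) standardGeneric("detectionP"))
#' @export
setMethod("detectionP", "ReprogExperiment",
          function(object) assay(object, "detectionP"))

#' @describeIn ReprogExperiment per-sample group labels
#' @export
setGeneric("sampleGroups", function(object) standardGeneric("sampleGroups"))
#' @export
setMethod("sampleGroups", "ReprogExperiment",
          function(object) colData(object)$group)

setMethod("show", "ReprogExperiment", function(object) {
    cat("ReprogExperiment:", nrow(object), "probes x", ncol(object),
        "samples\n")
    grp <- table(sampleGroups(object))
    cat("  groups:", paste(sprintf("%s(%d)", names(grp), grp),
                           collapse = ", "), "\n")
})

#' DetectionCalls: present/absent calls and the duplicate-present filter
#'
#' Result of thresholding detection p-values at a strict cutoff
#' (p < threshold means "present") plus the analysis set of probes present
#' in both duplicates of at least one sample group.
#'
#' @slot present logical probe x sample matrix.
#' @slot analysisSet character vector of probe ids passing the filter.
#' @slot threshold numeric detection cutoff (default 0.01).
#' @export
setClass("DetectionCalls",
         representation(present = "matrix", analysisSet = "character",
                        threshold = "numeric"))

setValidity("DetectionCalls", function(object) {
    msg <- NULL
    if (!is.logical(object@present))
        msg <- c(msg, "'present' must be a logical matrix")
    if (!all(object@analysisSet %in% rownames(object@present)))
        msg <- c(msg, "analysisSet must be a subset of probe ids")
    if (length(object@threshold) != 1L || object@threshold <= 0 ||
        object@threshold > 1)
        msg <- c(msg, "threshold must be a single value in (0, 1]")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "DetectionCalls", function(object) {
    cat("DetectionCalls: p <", object@threshold, "=> present\n")
    cat("  ", nrow(object@present), "probes,", ncol(object@present),
        "samples;", length(object@analysisSet),
        "probes in the analysis set\n")
})

#' @describeIn DetectionCalls probe ids passing the duplicate-present filter
#' @param object a DetectionCalls
#' @export
setGeneric("analysisSet", function(object) standardGeneric("analysisSet"))
#' @export
setMethod("analysisSet", "DetectionCalls", function(object) object@analysisSet)

#' @describeIn DetectionCalls logical present/absent matrix
#' @export
setGeneric("presentCalls", function(object) standardGeneric("presentCalls"))
#' @export
setMethod("presentCalls", "DetectionCalls", function(object) object@present)

#' FuzzyClusterResult: soft partition of expression profiles
#'
#' @slot centroids c x p matrix of cluster centre profiles.
#' @slot membership n x c matrix of memberships; each row sums to 1.
#' @slot objective numeric vector, the fuzzy within-cluster objective after
#'   each iteration (non-increasing).
#' @slot nIter number of iterations run.
#' @slot converged whether the centroid shift fell below tolerance.
#' @export
setClass("FuzzyClusterResult",
         representation(centroids = "matrix", membership = "matrix",
                        objective = "numeric", nIter = "integer",
                        converged = "logical"))

setValidity("FuzzyClusterResult", function(object) {
    msg <- NULL
    if (ncol(object@membership) != nrow(object@centroids))
        msg <- c(msg, "membership columns must match centroid rows")
    if (nrow(object@centroids) < 2L)
        msg <- c(msg, "at least two clusters required")
    if (any(!is.finite(object@centroids)))
        msg <- c(msg, "centroids must be finite")
    rs <- rowSums(object@membership)
    if (any(abs(rs - 1) > 1e-9))
        msg <- c(msg, "membership rows must sum to 1 (+/- 1e-9)")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "FuzzyClusterResult", function(object) {
    cat("FuzzyClusterResult:", nrow(object@membership), "profiles,",
        nrow(object@centroids), "clusters;",
        object@nIter, "iterations;",
        if (object@converged) "converged" else "not converged", "\n")
})

#' @describeIn FuzzyClusterResult membership matrix accessor
#' @param object a FuzzyClusterResult
#' @export
setGeneric("membership", function(object) standardGeneric("membership"))
#' @export
setMethod("membership", "FuzzyClusterResult",
          function(object) object@membership)

#' @describeIn FuzzyClusterResult centroid matrix accessor
#' @export
setGeneric("centroids", function(object) standardGeneric("centroids"))
#' @export
setMethod("centroids", "FuzzyClusterResult", function(object) object@centroids)

#' InteractionNetwork: typed mixed graph with node roles
#'
#' A mixed protein-interaction / regulatory graph. \code{ppi} edges are
#' undirected (traversable both ways); \code{reg} edges are directed
#' regulator -> target. Node roles mark the reprogramming factors as
#' \code{source} and the pluripotency endpoint genes as \code{sink}; all
#' other nodes are \code{other}.
#'
#' @slot nodes character vector of node ids.
#' @slot edges data.frame with columns \code{from}, \code{type}
#'   (\code{"ppi"} or \code{"reg"}), \code{to}.
#' @slot roles named character vector over nodes with values
#'   \code{"source"}, \code{"sink"} or \code{"other"}.
#' @export
setClass("InteractionNetwork",
         representation(nodes = "character", edges = "data.frame",
                        roles = "character"))

setValidity("InteractionNetwork", function(object) {
    msg <- NULL
    e <- object@edges
    if (!all(c("from", "type", "to") %in% colnames(e)))
        msg <- c(msg, "edges need columns from, type, to")
    else {
        if (!all(e$type %in% c("ppi", "reg")))
            msg <- c(msg, "edge types must be 'ppi' or 'reg'")
        if (any(e$from == e$to))
            msg <- c(msg, "self-loops are not allowed")
        if (!all(c(e$from, e$to) %in% object@nodes))
            msg <- c(msg, "edge endpoints must be declared nodes")
    }
    if (!setequal(names(object@roles), object@nodes) ||
        !all(object@roles %in% c("source", "sink", "other")))
        msg <- c(msg, "roles must assign source/sink/other to every node")
    if (is.null(msg)) TRUE else msg
})

#' Construct an InteractionNetwork
#'
#' @param edges data.frame with columns \code{from}, \code{type}, \code{to}.
#' @param sources,sinks character vectors of node ids (disjoint).
#' @param nodes optional full node list (defaults to edge endpoints plus
#'   declared sources/sinks, so isolated role nodes are kept).
#' @return An \linkS4class{InteractionNetwork}.
#' @export
InteractionNetwork <- function(edges, sources = character(),
                               sinks = character(), nodes = NULL) {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (length(intersect(sources, sinks)))
        stop("sources and sinks must be disjoint")
    if (is.null(nodes))
        nodes <- unique(c(edges$from, edges$to, sources, sinks))
    roles <- setNames(rep("other", length(nodes)), nodes)
    roles[sources] <- "source"
    roles[sinks] <- "sink"
    new("InteractionNetwork", nodes = nodes,
        edges = edges[, c("from", "type", "to")], roles = roles)
}

setMethod("show", "InteractionNetwork", function(object) {
    cat("InteractionNetwork:", length(object@nodes), "nodes,",
        nrow(object@edges), "edges (",
        sum(object@edges$type == "ppi"), "ppi /",
        sum(object@edges$type == "reg"), "reg )\n")
    cat("  sources:", paste(networkRoles(object, "source"), collapse = ", "),
        "\n  sinks:  ", paste(networkRoles(object, "sink"), collapse = ", "),
        "\n")
})

#' Nodes holding a given role
#'
#' @param net an InteractionNetwork
#' @param role one of "source", "sink", "other"
#' @return character vector of node ids.
#' @export
networkRoles <- function(net, role) {
    names(net@roles)[net@roles == role]
}

#' @describeIn InteractionNetwork node ids
#' @param object an InteractionNetwork
#' @export
setGeneric("networkNodes", function(object) standardGeneric("networkNodes"))
#' @export
setMethod("networkNodes", "InteractionNetwork", function(object) object@nodes)

#' @describeIn InteractionNetwork typed edge table
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))
#' @export
setMethod("networkEdges", "InteractionNetwork", function(object) object@edges)
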