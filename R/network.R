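## Source-to-sink analysis of a mixed protein-interaction / regulatory
## graph: merge all shortest paths between the reprogramming factors
## (sources) and the pluripotency endpoint genes (sinks), and score
## intermediate nodes by a weighted betweenness variant — the number of
## passing shortest paths divided by their mean length, favouring nodes on
## many short paths.

#' @importFrom igraph graph_from_data_frame all_shortest_paths distances V
NULL

## directed igraph view: ppi edges become reciprocal arcs, reg edges stay
## regulator -> target; with undirectedAll every edge is reciprocal
asDirectedIgraph <- function(net, undirectedAll = FALSE) {
    e <- networkEdges(net)
    both <- undirectedAll | e$type == "ppi"
    arcs <- rbind(data.frame(from = e$from, to = e$to),
                  data.frame(from = e$to[both], to = e$from[both]))
    igraph::graph_from_data_frame(arcs, directed = TRUE,
                                  vertices = networkNodes(net))
}

## hop distance between two nodes under mixed-graph semantics
mixedDistance <- function(net, from, to, undirectedAll = FALSE) {
    g <- asDirectedIgraph(net, undirectedAll)
    as.vector(igraph::distances(g, v = from, to = to, mode = "out"))
}

#' Enumerate all source-to-sink shortest paths
#'
#' All shortest paths for every (source, sink) pair under mixed-graph
#' semantics: ppi edges traversable both ways, regulatory edges forward
#' only. Unreachable pairs contribute nothing.
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @param sources,sinks node ids (default: the network's declared roles).
#' @param undirectedAll treat every edge as undirected.
#' @return list of character vectors (ordered node sequences), sorted by
#'   source id, sink id, then lexicographically by path.
#' @export
sourceSinkPaths <- function(net, sources = networkRoles(net, "source"),
                            sinks = networkRoles(net, "sink"),
                            undirectedAll = FALSE) {
    unknown <- setdiff(c(sources, sinks), networkNodes(net))
    if (length(unknown))
        stop("unknown source/sink id(s): ", paste(unknown, collapse = ", "))
    g <- asDirectedIgraph(net, undirectedAll)
    paths <- list()
    for (s in sources) {
        reach <- sinks[is.finite(as.vector(
            igraph::distances(g, v = s, to = sinks, mode = "out")))]
        if (length(reach) < length(sinks))
            message("source ", s, ": ", length(sinks) - length(reach),
                    " sink(s) unreachable")
        for (t in reach) {
            sp <- igraph::all_shortest_paths(g, from = s, to = t,
                                             mode = "out")$vpaths
            paths <- c(paths, lapply(sp, function(p) names(p)))
        }
    }
    key <- vapply(paths, function(p)
        paste(p[1], p[length(p)], paste(p, collapse = ">"), sep = "\r"),
        character(1))
    paths[order(key)]
}

#' Merge all source-to-sink shortest paths into a subnetwork
#'
#' The union of the nodes and (original typed) edges of every shortest path
#' between the sources and the sinks. A pair joined by a direct edge
#' contributes only its two endpoints.
#'
#' @inheritParams sourceSinkPaths
#' @return An \linkS4class{InteractionNetwork} restricted to the merged
#'   paths; roles are inherited.
#' @export
buildSubnetwork <- function(net, sources = networkRoles(net, "source"),
                            sinks = networkRoles(net, "sink"),
                            undirectedAll = FALSE) {
    paths <- sourceSinkPaths(net, sources, sinks, undirectedAll)
    nodes <- unique(unlist(paths))
    e <- networkEdges(net)
    used <- rep(FALSE, nrow(e))
    for (p in paths) {
        for (i in seq_len(length(p) - 1L)) {
            a <- p[i]; b <- p[i + 1L]
            used <- used | (e$from == a & e$to == b) |
                (e$type == "ppi" & e$from == b & e$to == a)
        }
    }
    sub <- e[used, , drop = FALSE]
    InteractionNetwork(sub, intersect(sources, nodes),
                       intersect(sinks, nodes), nodes = nodes)
}

#' Weighted shortest-path betweenness node score
#'
#' For each node outside the source/sink sets: \code{pathCount} is the
#' number of source-to-sink shortest paths containing it as an interior
#' node (accumulated across all pairs), \code{meanPathLength} the average
#' hop length of exactly those paths, and
#' \code{score = pathCount / meanPathLength} (0 when no path passes).
#' Sources and sinks are reported with NA scores.
#'
#' @inheritParams sourceSinkPaths
#' @return data.frame: node, role, pathCount, meanPathLength, score; one
#'   row per network node.
#' @export
scoreNodes <- function(net, sources = networkRoles(net, "source"),
                       sinks = networkRoles(net, "sink"),
                       undirectedAll = FALSE) {
    paths <- sourceSinkPaths(net, sources, sinks, undirectedAll)
    nodes <- networkNodes(net)
    cnt <- setNames(numeric(length(nodes)), nodes)
    lenSum <- cnt
    for (p in paths) {
        len <- length(p) - 1L
        interior <- setdiff(p[-c(1, length(p))], c(sources, sinks))
        cnt[interior] <- cnt[interior] + 1
        lenSum[interior] <- lenSum[interior] + len
    }
    meanLen <- ifelse(cnt > 0, lenSum / cnt, NA_real_)
    score <- ifelse(cnt > 0, cnt / meanLen, 0)
    terminal <- nodes %in% c(sources, sinks)
    score[terminal] <- NA_real_
    meanLen[terminal] <- NA_real_
    cnt[terminal] <- NA_real_
    data.frame(node = nodes, role = unname(net@roles[nodes]),
               pathCount = unname(cnt), meanPathLength = unname(meanLen),
               score = unname(score), row.names = NULL,
               stringsAsFactors = FALSE)
}

#' Classify scored nodes as high or low
#'
#' Nodes scoring at or above the \code{highQuantile} quantile of the
#' positive scores are "high"; the rest (including zero-score nodes) are
#' "low". Ties at the boundary go high; source/sink rows keep NA.
#'
#' @param scores output of \code{\link{scoreNodes}}.
#' @param highQuantile quantile of positive scores (default 0.75).
#' @return the input with a \code{class} column added.
#' @export
classifyNodes <- function(scores, highQuantile = 0.75) {
    sc <- scores$score
    if (all(is.na(sc)))
        stop("no scored node to classify")
    pos <- sc[!is.na(sc) & sc > 0]
    if (length(pos) == 0L) {
        scores$class <- ifelse(is.na(sc), NA_character_, "low")
        return(scores)
    }
    thr <- stats::quantile(pos, highQuantile, names = FALSE)
    scores$class <- ifelse(is.na(sc), NA_character_,
                           ifelse(sc >= thr & sc > 0, "high", "low"))
    scores
}

#' Shortest paths through a named intermediate
#'
#' All source-to-sink shortest paths whose \emph{interior} contains
#' \code{via}, in deterministic order (source id, sink id, lexicographic
#' path).
#'
#' @inheritParams sourceSinkPaths
#' @param via node id required in the path interior.
#' @return list of character node sequences (possibly empty).
#' @export
pathsThrough <- function(net, sources = networkRoles(net, "source"),
                         sinks = networkRoles(net, "sink"), via,
                         undirectedAll = FALSE) {
    if (!via %in% networkNodes(net))
        stop("unknown node id: ", via)
    paths <- sourceSinkPaths(net, sources, sinks, undirectedAll)
    Filter(function(p) via %in% p[-c(1, length(p))], paths)
}

#' Read a SIF-like typed edge list and a node-role table
#'
#' Edge file: \code{node_a<TAB>type(ppi|reg)<TAB>node_b} per line. Role
#' file: \code{node<TAB>role(source|sink)}.
#'
#' @param sifFile path to the edge list.
#' @param rolesFile optional path to the roles table.
#' @return An \linkS4class{InteractionNetwork}.
#' @export
readSIF <- function(sifFile, rolesFile = NULL) {
    e <- utils::read.table(sifFile, sep = "\t", header = FALSE,
                           col.names = c("from", "type", "to"),
                           stringsAsFactors = FALSE)
    sources <- sinks <- character()
    if (!is.null(rolesFile)) {
        r <- utils::read.table(rolesFile, sep = "\t", header = FALSE,
                               col.names = c("node", "role"),
                               stringsAsFactors = FALSE)
        sources <- r$node[r$role == "source"]
        sinks <- r$node[r$role == "sink"]
    }
    InteractionNetwork(e, sources, sinks)
}

#' Export a scored network as GraphML
#'
#' Writes nodes with role/score/class attributes and typed edges; readable
#' by standard graph tools.
#'
#' @param net an \linkS4class{InteractionNetwork}.
#' @param scores classified score table (\code{\link{classifyNodes}}).
#' @param file output path.
#' @export
writeGraphML <- function(net, scores, file) {
    gs <- igraph::graph_from_data_frame(
        networkEdges(net)[, c("from", "to", "type")], directed = TRUE,
        vertices = data.frame(
            name = networkNodes(net),
            role = unname(net@roles[networkNodes(net)]),
            score = scores$score[match(networkNodes(net), scores$node)],
            class = scores$class[match(networkNodes(net), scores$node)],
            stringsAsFactors = FALSE))
    igraph::write_graph(gs, file, format = "graphml")
    invisible(file)
}

#' The packaged curated reprogramming network fixture
#'
#' A small hand-curated mixed network around the named relationships of the
#' reprogramming interaction map (POU5F1 -> FRAT2 regulatory; FRAT2-GSK3B,
#' GSK3B-MYCN, GSK3B-OTX2, MYC-GSK3B, KLF4-CREBBP, CREBBP-GLI3, GLI3-ZIC3
#' protein-protein; MYCN -> DNMT3A regulatory), with the four reprogramming
#' factors as sources and MYCN/OTX2/ZIC3/DNMT3A as sinks.
#'
#' @return An \linkS4class{InteractionNetwork}.
#' @export
reprogNetworkFixture <- function() {
    readSIF(system.file("extdata", "oskm_network.sif",
                        package = "earlyReprog"),
            system.file("extdata", "oskm_network_roles.tsv",
                        package = "earlyReprog"))
}
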