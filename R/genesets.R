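## Pluripotency-/fibroblast-associated gene sets from presence/absence
## calls, their activation across the time course, and simple term-based
## subsetting/enrichment.

#' Read / write gene sets in GMT format
#'
#' One set per line: \code{name<TAB>description<TAB>member...}.
#'
#' @param file path to a GMT file.
#' @return \code{readGMT}: named list of character vectors (the
#'   descriptions are kept as an attribute).
#' @export
readGMT <- function(file) {
    lines <- readLines(file, warn = FALSE)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    sets <- lapply(parts, function(p) unique(p[-(1:2)]))
    names(sets) <- vapply(parts, `[`, character(1), 1L)
    attr(sets, "description") <- vapply(parts, `[`, character(1), 2L)
    sets
}

#' @rdname readGMT
#' @param sets named list of character vectors.
#' @param description per-set description strings (recycled).
#' @export
writeGMT <- function(sets, file, description = "") {
    description <- rep_len(description, length(sets))
    lines <- mapply(function(nm, d, members)
        paste(c(nm, d, members), collapse = "\t"),
        names(sets), description, sets)
    writeLines(lines, file)
    invisible(file)
}

#' Derive pluripotency- and fibroblast-associated probe sets
#'
#' Pluripotency-associated: present (group-level, i.e. in both replicates)
#' in \emph{every} pluripotent group and absent in every donor replicate.
#' Fibroblast-associated is the mirror image. Under \code{mode = "any"} a
#' probe needs group-level presence in at least one pluripotent group.
#'
#' @param calls a \linkS4class{DetectionCalls}.
#' @param groups per-sample group labels in column order.
#' @param donorGroup donor label.
#' @param pluriGroups pluripotent group labels (all required present).
#' @param mode \code{"all"} (strict, default) or \code{"any"}.
#' @return list with character vectors \code{pluripotencyAssociated} and
#'   \code{fibroblastAssociated} (disjoint, both within the analysis set).
#' @export
deriveAssociatedSets <- function(calls, groups, donorGroup = "donor",
                                 pluriGroups = c("iPS", "ES"),
                                 mode = c("all", "any")) {
    mode <- match.arg(mode)
    need <- c(donorGroup, pluriGroups)
    if (!all(need %in% groups))
        stop("missing required group(s): ",
             paste(setdiff(need, groups), collapse = ", "))
    present <- presentCalls(calls)
    gp <- groupPresence(calls, groups)
    donorAbsent <- rowSums(present[, groups == donorGroup,
                                   drop = FALSE]) == 0L
    donorPresent <- gp[, donorGroup]
    pluriMat <- gp[, pluriGroups, drop = FALSE]
    pluriPresent <- if (mode == "all") rowSums(!pluriMat) == 0L
                    else rowSums(pluriMat) > 0L
    absentMat <- vapply(pluriGroups, function(g)
        rowSums(present[, groups == g, drop = FALSE]) == 0L,
        logical(nrow(present)))
    pluriAbsent <- rowSums(!absentMat) == 0L
    ids <- rownames(present)
    keep <- analysisSet(calls)
    list(pluripotencyAssociated =
             intersect(ids[pluriPresent & donorAbsent], keep),
         fibroblastAssociated =
             intersect(ids[donorPresent & pluriAbsent], keep))
}

#' Activation time course of the associated gene sets
#'
#' Per group, the fraction of each set that is group-level present (present
#' in both replicates). By construction the pluripotency-associated fraction
#' is 0 in the donor group and the fibroblast-associated fraction is 0 in
#' the pluripotent groups.
#'
#' @param calls a \linkS4class{DetectionCalls}.
#' @param partition output of \code{\link{deriveAssociatedSets}}.
#' @param groups per-sample group labels in column order.
#' @param groupOrder optional ordering of groups in the output.
#' @return data.frame with columns group, pluripotencyFraction,
#'   fibroblastFraction.
#' @export
activationTimecourse <- function(calls, partition, groups,
                                 groupOrder = unique(groups)) {
    np <- length(partition$pluripotencyAssociated)
    nf <- length(partition$fibroblastAssociated)
    if (np == 0L && nf == 0L) {
        warning("empty gene-set partition; returning empty time course")
        return(data.frame(group = character(),
                          pluripotencyFraction = numeric(),
                          fibroblastFraction = numeric()))
    }
    gp <- groupPresence(calls, groups)[, groupOrder, drop = FALSE]
    frac <- function(set) if (length(set) == 0L) rep(NA_real_, ncol(gp))
        else colSums(gp[set, , drop = FALSE]) / length(set)
    data.frame(group = groupOrder,
               pluripotencyFraction = frac(partition$pluripotencyAssociated),
               fibroblastFraction = frac(partition$fibroblastAssociated),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Subset the pluripotency-associated set by surface-annotation terms
#'
#' Returns the pluripotency-associated probes annotated with either of the
#' membrane/surface cellular-component terms (the candidate FACS markers).
#'
#' @param partition output of \code{\link{deriveAssociatedSets}}.
#' @param annotation named list, term -> member ids (e.g. from
#'   \code{\link{readGMT}}).
#' @param terms annotation terms selecting the surface subset.
#' @return character vector, a subset of the pluripotency-associated set.
#' @export
annotateSurface <- function(partition, annotation,
                            terms = c("integral to membrane",
                                      "cell surface")) {
    known <- intersect(terms, names(annotation))
    if (length(known) == 0L) {
        warning("none of the requested terms found in the annotation")
        return(character())
    }
    intersect(partition$pluripotencyAssociated,
              unique(unlist(annotation[known], use.names = FALSE)))
}

#' Hypergeometric term enrichment
#'
#' Classic one-sided (upper-tail) hypergeometric test of the overlap between
#' the query set and each annotation term within the universe, adjusted by
#' Benjamini-Hochberg across the tested terms.
#'
#' @param query character ids, a subset of \code{universe}.
#' @param universe character ids forming the sampling frame.
#' @param annotation named list, term -> member ids.
#' @return data.frame with columns term, overlap, termSize, querySize,
#'   universeSize, pValue, adjPValue, sorted by pValue.
#' @export
enrichHypergeometric <- function(query, universe, annotation) {
    if (!all(query %in% universe))
        stop("query must be a subset of the universe")
    query <- unique(query)
    universe <- unique(universe)
    res <- lapply(names(annotation), function(tm) {
        members <- intersect(annotation[[tm]], universe)
        K <- length(members)
        x <- length(intersect(query, members))
        p <- stats::phyper(x - 1L, K, length(universe) - K, length(query),
                           lower.tail = FALSE)
        data.frame(term = tm, overlap = x, termSize = K,
                   querySize = length(query),
                   universeSize = length(universe), pValue = p,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    out$adjPValue <- adjustBH(out$pValue)
    out[order(out$pValue), , drop = FALSE]
}
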