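## Plain-text interchange: the GenomeStudio-like expression TSV dialect
## (per-sample AVG_Signal / Detection_Pval column pairs), the sample->group
## mapping table, and a loader for GEO series-matrix style exports.

#' Write / read the expression TSV dialect
#'
#' Header \code{probe_id<TAB><sample>.AVG_Signal<TAB><sample>.Detection_Pval
#' ...}, one probe per row, UTF-8, decimal point. The sample-to-group
#' mapping travels in a separate three-column TSV
#' (\code{sample<TAB>group<TAB>replicate}).
#'
#' @param object a \linkS4class{ReprogExperiment}.
#' @param exprFile,sampleFile output paths.
#' @export
writeExpressionTSV <- function(object, exprFile, sampleFile = NULL) {
    ex <- intensities(object)
    dp <- detectionP(object)
    out <- data.frame(probe_id = rownames(ex), check.names = FALSE,
                      stringsAsFactors = FALSE)
    for (j in seq_len(ncol(ex))) {
        out[[paste0(colnames(ex)[j], ".AVG_Signal")]] <- ex[, j]
        out[[paste0(colnames(ex)[j], ".Detection_Pval")]] <- dp[, j]
    }
    utils::write.table(out, exprFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(sampleFile)) {
        cd <- colData(object)
        utils::write.table(
            data.frame(sample = rownames(cd), group = cd$group,
                       replicate = cd$replicate),
            sampleFile, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(exprFile)
}

#' @rdname writeExpressionTSV
#' @return \code{readExpressionTSV}: a \linkS4class{ReprogExperiment}.
#' @export
readExpressionTSV <- function(exprFile, sampleFile) {
    tab <- utils::read.table(exprFile, sep = "\t", header = TRUE,
                             check.names = FALSE, stringsAsFactors = FALSE)
    info <- utils::read.table(sampleFile, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
    sig <- grep("\\.AVG_Signal$", colnames(tab), value = TRUE)
    det <- grep("\\.Detection_Pval$", colnames(tab), value = TRUE)
    samples <- sub("\\.AVG_Signal$", "", sig)
    if (!setequal(samples, sub("\\.Detection_Pval$", "", det)))
        stop("AVG_Signal and Detection_Pval columns do not pair up")
    det <- paste0(samples, ".Detection_Pval")
    ex <- as.matrix(tab[, sig, drop = FALSE])
    dp <- as.matrix(tab[, det, drop = FALSE])
    dimnames(ex) <- dimnames(dp) <- list(tab$probe_id, samples)
    m <- match(samples, info$sample)
    if (anyNA(m))
        stop("sample table misses: ",
             paste(samples[is.na(m)], collapse = ", "))
    ReprogExperiment(ex, dp, group = info$group[m],
                     replicate = info$replicate[m])
}

#' Load a GEO series-matrix style export with detection columns
#'
#' Parses a series-matrix text file (metadata lines prefixed with
#' \code{!}; the probe table between \code{!series_matrix_table_begin} and
#' \code{!series_matrix_table_end}) whose table carries, per sample, a
#' signal column and a detection p-value column (name containing
#' \code{Detection}). Group/replicate assignment is supplied by the caller;
#' intensities are used as stored (apply \code{\link{quantileNormalize}}
#' and/or log2 yourself if the export is raw scale).
#'
#' @param path series-matrix text file.
#' @param group,replicate per-sample annotation, in column order.
#' @return A \linkS4class{ReprogExperiment}.
#' @export
loadGeoSeries <- function(path, group, replicate) {
    lines <- readLines(path, warn = FALSE)
    beg <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    body <- if (length(beg) && length(end))
        lines[(beg + 1L):(end - 1L)] else lines[!grepl("^!", lines)]
    tab <- utils::read.table(text = body, sep = "\t", header = TRUE,
                             check.names = FALSE, stringsAsFactors = FALSE,
                             quote = "\"")
    detCols <- grep("Detection", colnames(tab), value = TRUE)
    if (length(detCols) == 0L)
        stop("no detection p-value columns found; this loader requires a ",
             "series-matrix export that retains per-sample Detection ",
             "columns")
    idCol <- colnames(tab)[1]
    sigCols <- setdiff(colnames(tab), c(idCol, detCols))
    if (length(sigCols) != length(detCols))
        stop("signal and detection columns do not pair up")
    ex <- as.matrix(tab[, sigCols, drop = FALSE])
    dp <- as.matrix(tab[, detCols, drop = FALSE])
    dimnames(ex) <- dimnames(dp) <- list(tab[[idCol]], sigCols)
    ReprogExperiment(ex, dp, group = group, replicate = replicate)
}
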