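# Plain-text I/O: TSV tables for intensities, chip layouts, annotation,
# expression results and marker panels; JSON for planted truth. All
# readers validate headers strictly and preserve identifier case.

.requireCols <- function(df, cols, what) {
    miss <- setdiff(cols, colnames(df))
    if (length(miss))
        stop(what, " is missing required column(s): ",
             paste(miss, collapse = ", "))
    invisible(TRUE)
}

.fread <- function(path) {
    as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                    colClasses = NULL))
}

.fwrite <- function(df, path) {
    data.table::fwrite(df, path, sep = "\t", quote = FALSE)
    invisible(path)
}

#' Write / read a probe-level intensity matrix
#'
#' The on-disk layout has one row per physical probe (PM and MM rows
#' separately, identified by \code{probe_id}) and one column per sample;
#' the companion chip-layout file maps probes back to (probeset, pair,
#' role).
#'
#' @param x A \code{\link{ProbePairSet}}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly (writer); a \code{ProbePairSet}
#'   (reader).
#' @export
writeIntensityTSV <- function(x, path) {
    stopifnot(is(x, "ProbePairSet"))
    rd <- rowData(x)
    pid <- sprintf("%s.%d", rd$probeset_id, rd$pair_index)
    df <- data.frame(probe_id = c(paste0(pid, ".pm"), paste0(pid, ".mm")),
                     rbind(pmIntensity(x), mmIntensity(x)),
                     check.names = FALSE)
    .fwrite(df, path)
}

#' @rdname writeIntensityTSV
#' @param layout Chip layout data.frame (long form, as written by
#'   \code{\link{writeChipLayoutTSV}}).
#' @export
readIntensityTSV <- function(path, layout) {
    df <- .fread(path)
    .requireCols(df, "probe_id", "intensity matrix")
    if (anyDuplicated(df$probe_id)) stop("duplicate probe_id in ", path)
    if (anyNA(df[-1])) stop("missing values are forbidden in intensity matrices")
    mat <- as.matrix(df[-1])
    rownames(mat) <- df$probe_id
    .requireCols(layout, c("probe_id", "probeset_id", "pair_index", "role"),
                 "chip layout")
    pmrows <- layout[layout$role == "PM", ]
    mmrows <- layout[layout$role == "MM", ]
    key <- function(l) paste(l$probeset_id, l$pair_index)
    mmrows <- mmrows[match(key(pmrows), key(mmrows)), ]
    miss <- setdiff(c(pmrows$probe_id, mmrows$probe_id), rownames(mat))
    if (length(miss))
        stop("probes referenced by layout missing from matrix: ",
             paste(head(miss), collapse = ", "))
    ProbePairSet(mat[pmrows$probe_id, , drop = FALSE],
                 mat[mmrows$probe_id, , drop = FALSE],
                 probesetId = pmrows$probeset_id,
                 pairIndex = pmrows$pair_index)
}

#' Write / read a chip layout
#'
#' Long-form layout with one row per physical probe: probe_id,
#' probeset_id, pair_index, role (PM/MM). The simulator's frozen probe
#' affinity is carried in an optional \code{affinity} column.
#'
#' @param layout Pair-level layout from \code{\link{makeChipLayout}}.
#' @param path TSV path.
#' @export
writeChipLayoutTSV <- function(layout, path) {
    pid <- sprintf("%s.%d", layout$probeset_id, layout$pair_index)
    long <- data.frame(
        probe_id = c(paste0(pid, ".pm"), paste0(pid, ".mm")),
        probeset_id = rep(layout$probeset_id, 2),
        pair_index = rep(layout$pair_index, 2),
        role = rep(c("PM", "MM"), each = nrow(layout)),
        gene_id = rep(layout$gene_id, 2),
        affinity = rep(layout$affinity, 2))
    .fwrite(long, path)
}

#' @rdname writeChipLayoutTSV
#' @export
readChipLayoutTSV <- function(path) {
    df <- .fread(path)
    .requireCols(df, c("probe_id", "probeset_id", "pair_index", "role"),
                 "chip layout")
    if (anyDuplicated(df$probe_id)) stop("duplicate probe_id in ", path)
    if (!all(df$role %in% c("PM", "MM"))) stop("role must be PM or MM")
    df
}

#' Write / read probeset-to-gene annotation
#' @param annotation data.frame with probeset_id, gene_id.
#' @param path TSV path.
#' @export
writeAnnotationTSV <- function(annotation, path) {
    .requireCols(annotation, c("probeset_id", "gene_id"), "annotation")
    .fwrite(annotation[, c("probeset_id", "gene_id")], path)
}

#' @rdname writeAnnotationTSV
#' @export
readAnnotationTSV <- function(path) {
    df <- .fread(path)
    .requireCols(df, c("probeset_id", "gene_id"), "annotation")
    if (anyDuplicated(df$probeset_id))
        stop("duplicate probeset_id in annotation")
    df
}

#' Write / read normalized expression results
#'
#' One row per probeset with per-sample signal, detection p and call
#' columns (\code{<sample>.signal}, \code{<sample>.p}, \code{<sample>.call}).
#'
#' @param x A \code{\link{MAS5Set}}.
#' @param path TSV path.
#' @export
writeExpressionTSV <- function(x, path) {
    stopifnot(is(x, "MAS5Set"))
    s <- exprSignal(x); p <- detectionP(x); cl <- detectionCalls(x)
    df <- data.frame(probeset_id = rownames(s), check.names = FALSE)
    for (j in colnames(s)) {
        df[[paste0(j, ".signal")]] <- s[, j]
        df[[paste0(j, ".p")]] <- p[, j]
        df[[paste0(j, ".call")]] <- cl[, j]
    }
    .fwrite(df, path)
}

#' @rdname writeExpressionTSV
#' @export
readExpressionTSV <- function(path) {
    df <- .fread(path)
    .requireCols(df, "probeset_id", "expression table")
    samp <- unique(sub("\\.(signal|p|call)$", "",
                       grep("\\.(signal|p|call)$", colnames(df), value = TRUE)))
    get <- function(suffix, mode) {
        cols <- paste0(samp, ".", suffix)
        .requireCols(df, cols, "expression table")
        m <- as.matrix(df[cols])
        dimnames(m) <- list(df$probeset_id, samp)
        storage.mode(m) <- mode
        m
    }
    MAS5Set(signal = get("signal", "double"),
            detectionP = get("p", "double"),
            call = get("call", "character"),
            scaleFactors = setNames(rep(NA_real_, length(samp)), samp))
}

#' Read a marker panel
#'
#' Two-column TSV (cell_type, gene_id) giving marker genes per cell type.
#'
#' @param path TSV path.
#' @return Named list cell type -> character vector of markers.
#' @export
readMarkersTSV <- function(path) {
    df <- .fread(path)
    .requireCols(df, c("cell_type", "gene_id"), "marker panel")
    bad <- setdiff(unique(df$cell_type), .CELL_TYPES)
    if (length(bad)) stop("unknown cell type(s): ", paste(bad, collapse = ", "))
    split(df$gene_id, df$cell_type)
}

#' Serialize / restore planted truth
#'
#' Lossless JSON round trip of a \code{\link{SyntheticTruth}}.
#'
#' @param truth A \code{SyntheticTruth}.
#' @param path JSON path.
#' @export
writeTruth <- function(truth, path) {
    stopifnot(is(truth, "SyntheticTruth"))
    obj <- list(planted_deg = truth@plantedDeg,
                planted_class = as.list(truth@plantedClass),
                planted_ectopic = truth@plantedEctopic,
                compositions = lapply(truth@compositions, as.list),
                noise = truth@noise,
                seed = truth@seed)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    ec <- obj$planted_ectopic
    if (is.null(ec) || !length(ec))
        ec <- data.frame(gene_id = character(), cell_type = character())
    pc <- unlist(obj$planted_class)
    if (is.null(pc)) pc <- character()
    SyntheticTruth(
        plantedDeg = as.character(obj$planted_deg),
        plantedClass = pc,
        plantedEctopic = as.data.frame(ec),
        compositions = lapply(obj$compositions, unlist),
        noise = obj$noise,
        seed = obj$seed)
}

#' Write / read a cell-type reference
#' @param reference A \code{\link{CellTypeReference}}.
#' @param path TSV path.
#' @export
writeReferenceTSV <- function(reference, path) {
    df <- data.frame(gene_id = rownames(reference),
                     refSignal(reference),
                     enrichment_class = refClass(reference),
                     check.names = FALSE)
    .fwrite(df, path)
}

#' @rdname writeReferenceTSV
#' @param factor Enrichment factor recorded with the restored object.
#' @export
readReferenceTSV <- function(path, factor = 4) {
    df <- .fread(path)
    .requireCols(df, c("gene_id", .CELL_TYPES), "reference")
    m <- as.matrix(df[.CELL_TYPES])
    rownames(m) <- df$gene_id
    CellTypeReference(m, factor = factor)
}
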