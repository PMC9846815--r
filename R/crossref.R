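# Cross-referencing disease fold changes in isolated cell-type datasets
# and detecting ectopic expression against the contamination envelope.
#
# An isolated cell-type dataset (e.g. LCM-captured astrocytes) carries
# some contamination from adjacent cell types, so a gene whose home type
# is microglia can show an apparent fold change in a diseased astrocyte
# dataset purely because activated microglia contaminate it. The envelope
# of fold changes shown by bona fide home-type markers bounds what
# contamination alone can explain; a gene far above that envelope is
# called ectopically induced.

#' Gene-level fold changes between disease and control datasets
#'
#' Ratio of disease to control mean signal per gene, for one isolated
#' cell-type dataset pair. Both datasets must be normalized to the same
#' scaling target.
#'
#' @param disease,control \code{\link{MAS5Set}} objects or gene x sample
#'   matrices over the same gene universe.
#' @param annotation Optional probeset -> gene annotation (max collapse)
#'   applied to \code{MAS5Set} inputs.
#' @return Named numeric vector of fold changes.
#' @export
cellTypeFoldChanges <- function(disease, control, annotation = NULL) {
    toMat <- function(d) {
        if (is(d, "MAS5Set")) {
            if (!is.null(annotation)) geneSignals(d, annotation)
            else exprSignal(d)
        } else as.matrix(d)
    }
    if (is(disease, "MAS5Set") && is(control, "MAS5Set")) {
        t1 <- metadata(disease)$params$scaleTarget
        t2 <- metadata(control)$params$scaleTarget
        if (!is.null(t1) && !is.null(t2) && !identical(t1, t2))
            stop("disease and control datasets have different scaling targets")
    }
    d <- toMat(disease); ctl <- toMat(control)
    shared <- intersect(rownames(d), rownames(ctl))
    if (!length(shared)) stop("no shared genes")
    rowMeans(d[shared, , drop = FALSE]) /
        rowMeans(ctl[shared, , drop = FALSE])
}

#' Assemble a disease fold-change table
#'
#' Column-binds per-dataset fold-change vectors (one per cell type and
#' timepoint, e.g. \code{microglia_P90}, \code{astrocyte_P120}) into a
#' gene x dataset matrix.
#'
#' @param fcs Named list of fold-change vectors from
#'   \code{\link{cellTypeFoldChanges}}; names must be unique dataset
#'   labels.
#' @return Gene x dataset fold-change matrix (shared genes only).
#' @export
diseaseFcTable <- function(fcs) {
    stopifnot(is.list(fcs), length(fcs) >= 1,
              !is.null(names(fcs)), !anyDuplicated(names(fcs)))
    shared <- Reduce(intersect, lapply(fcs, names))
    out <- vapply(fcs, function(v) v[shared], numeric(length(shared)))
    rownames(out) <- shared
    if (any(out <= 0)) stop("fold changes must be > 0")
    out
}

#' Contamination envelope of foreign-type markers
#'
#' The range (max, min) of fold changes shown by a set of foreign
#' cell-type markers inside a host dataset: an upper bound on the fold
#' change that contamination by that foreign type can produce. Fewer than
#' two available markers make the envelope unreliable and are refused.
#'
#' @param fcTable Matrix from \code{\link{diseaseFcTable}}.
#' @param hostDataset Column name of the host dataset.
#' @param markers Character vector of foreign-type marker gene ids.
#' @return Named numeric c(envelope_max, envelope_min).
#' @export
#' @examples
#' tab <- matrix(c(0.6, 3.1, 8.5), 3, 1,
#'               dimnames = list(c("Cd68", "Aif1", "Itgam"), "astrocyte_P90"))
#' contaminationEnvelope(tab, "astrocyte_P90", c("Cd68", "Aif1", "Itgam"))
contaminationEnvelope <- function(fcTable, hostDataset, markers) {
    stopifnot(hostDataset %in% colnames(fcTable))
    markers <- intersect(markers, rownames(fcTable))
    if (length(markers) < 2)
        stop("need at least 2 markers present in the table")
    v <- fcTable[markers, hostDataset]
    c(envelope_max = max(v), envelope_min = min(v))
}

#' Detect ectopic expression in a host dataset
#'
#' For each candidate gene whose home enrichment class differs from the
#' host dataset's cell type, compares the gene's disease fold change with
#' the contamination envelope of its home-type markers in the same
#' dataset. The gene is flagged ectopic when its fold change exceeds
#' \code{k} times the envelope maximum and an absolute floor. Genes whose
#' home class equals the host type, or is Unclassified, yield no call.
#'
#' @param genes Character vector of candidate gene ids.
#' @param fcTable Matrix from \code{\link{diseaseFcTable}}.
#' @param reference A \code{\link{CellTypeReference}} supplying home
#'   classes.
#' @param markerPanel Named list cell type -> marker gene ids used for
#'   envelopes (a gene under test is excluded from its own envelope).
#' @param hostDataset Column of \code{fcTable} to examine.
#' @param hostCellType Cell type of the host dataset.
#' @param k Envelope multiplier (default 3).
#' @param floorFc Absolute minimum fold change (default 10).
#' @return data.frame with one row per assessable gene: gene_id,
#'   home_class, host_dataset, gene_fc, envelope_max, k, floor and flag.
#' @export
detectEctopic <- function(genes, fcTable, reference, markerPanel,
                          hostDataset, hostCellType, k = 3, floorFc = 10) {
    stopifnot(is(reference, "CellTypeReference"),
              hostCellType %in% .CELL_TYPES, k > 0, floorFc > 0)
    cls <- refClass(reference)
    rows <- lapply(genes, function(g) {
        home <- cls[g]
        if (is.na(home) || home == .UNCLASSIFIED || home == hostCellType)
            return(NULL)
        if (!g %in% rownames(fcTable)) return(NULL)
        markers <- setdiff(markerPanel[[home]], g)
        env <- contaminationEnvelope(fcTable, hostDataset, markers)
        fc <- fcTable[g, hostDataset]
        data.frame(gene_id = g, home_class = unname(home),
                   host_dataset = hostDataset, gene_fc = unname(fc),
                   envelope_max = unname(env["envelope_max"]),
                   k = k, floor = floorFc,
                   flag = unname(fc > k * env["envelope_max"] & fc > floorFc))
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(gene_id = character(), home_class = character(),
                          host_dataset = character(), gene_fc = numeric(),
                          envelope_max = numeric(), k = numeric(),
                          floor = numeric(), flag = logical())
    rownames(out) <- NULL
    out
}
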