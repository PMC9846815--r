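# Integrated cell-type-specific transcriptome reference and the
# fold-ratio enrichment classifier.

#' Classify a gene's cell-type enrichment
#'
#' A gene is enriched in a cell type when that type's signal is at least
#' \code{factor} times the signal in every other analyzed type (the
#' fourfold rule of the Human Protein Atlas "cell type enriched"
#' definition, inclusive at the boundary). Ties at the maximum, or a
#' maximum below the required multiple of the runner-up, give
#' \code{"Unclassified"}. If all other types are zero and the maximum is
#' positive, the gene classifies to the maximum's type.
#'
#' @param values Named numeric vector of signals over the five
#'   \code{\link{cellTypes}()}.
#' @param factor Required ratio (>= 1; default 4).
#' @return A single class label.
#' @export
#' @examples
#' classifyEnrichment(c(motor_neuron = 100, neuron = 90, astrocyte = 80,
#'                      microglia = 500, oligodendrocyte = 70))
classifyEnrichment <- function(values, factor = 4) {
    stopifnot(factor >= 1, length(values) == 5L, all(is.finite(values)),
              all(values >= 0))
    if (!is.null(names(values))) values <- values[.CELL_TYPES]
    else names(values) <- .CELL_TYPES
    o <- order(values, decreasing = TRUE)
    mx <- values[o[1]]; second <- values[o[2]]
    if (mx == 0) return(.UNCLASSIFIED)
    if (second == 0) return(names(values)[o[1]])
    if (mx == second) return(.UNCLASSIFIED)
    if (mx >= factor * second) names(values)[o[1]] else .UNCLASSIFIED
}

# Collapse probeset-level signals to gene level, taking the maximum signal
# among a gene's probesets (conservative against probe dropout).
.collapseMax <- function(sig, annotation) {
    idx <- match(rownames(sig), annotation$probeset_id)
    keep <- !is.na(idx)
    sig <- sig[keep, , drop = FALSE]
    gene <- annotation$gene_id[idx[keep]]
    groups <- split(seq_len(nrow(sig)), gene)
    out <- do.call(rbind, lapply(groups, function(i) {
        if (length(i) == 1L) sig[i, ] else apply(sig[i, , drop = FALSE], 2L, max)
    }))
    colnames(out) <- colnames(sig)
    out
}

#' Gene-level signals from a normalized dataset
#'
#' Maps probesets to genes and collapses multiple probesets per gene by
#' taking the maximum signal per sample.
#'
#' @param x A \code{\link{MAS5Set}}.
#' @param annotation data.frame with probeset_id, gene_id.
#' @return Gene x sample signal matrix.
#' @export
geneSignals <- function(x, annotation) {
    stopifnot(is(x, "MAS5Set"),
              all(c("probeset_id", "gene_id") %in% colnames(annotation)))
    .collapseMax(exprSignal(x), annotation)
}

#' Build the integrated cell-type reference
#'
#' Combines one commonly-normalized expression dataset per cell type into
#' a gene x cell-type table of mean signals and classifies every gene's
#' enrichment. All datasets must have been scaled to the same target
#' (MAS5 global scaling), since the classifier compares signals across
#' datasets; mismatched targets are rejected.
#'
#' @param datasets Named list over the five \code{\link{cellTypes}()} of
#'   \code{\link{MAS5Set}} objects (or plain gene x sample matrices).
#' @param annotation Optional probeset -> gene annotation applied to
#'   \code{MAS5Set} inputs (max collapse).
#' @param factor Enrichment ratio (default 4).
#' @return A \code{\link{CellTypeReference}}. Genes absent from any
#'   dataset are dropped and listed in the \code{"missing_genes"}
#'   metadata entry.
#' @export
buildReference <- function(datasets, annotation = NULL, factor = 4) {
    stopifnot(identical(sort(names(datasets)), sort(.CELL_TYPES)))
    targets <- vapply(datasets, function(d)
        if (is(d, "MAS5Set")) metadata(d)$params$scaleTarget %||% NA_real_
        else NA_real_, numeric(1))
    tg <- unique(targets[!is.na(targets)])
    if (length(tg) > 1)
        stop("datasets were scaled to different targets: ",
             paste(tg, collapse = ", "))
    mats <- lapply(datasets[.CELL_TYPES], function(d) {
        if (is(d, "MAS5Set")) {
            if (!is.null(annotation)) geneSignals(d, annotation)
            else exprSignal(d)
        } else as.matrix(d)
    })
    shared <- Reduce(intersect, lapply(mats, rownames))
    allg <- unique(unlist(lapply(mats, rownames)))
    missing <- setdiff(allg, shared)
    m <- vapply(mats, function(x) rowMeans(x[shared, , drop = FALSE]),
                numeric(length(shared)))
    colnames(m) <- .CELL_TYPES
    ref <- CellTypeReference(m, factor = factor)
    metadata(ref)$missing_genes <- missing
    metadata(ref)$scale_target <- if (length(tg)) tg else NA_real_
    ref
}

#' Validate marker genes against the reference
#'
#' Classifies each marker with the reference's enrichment rule and checks
#' whether the label matches the marker's panel cell type. Markers below
#' detection in every cell type (all signals at or below
#' \code{minSignal}) are reported as non-informative rather than failed.
#'
#' @param reference A \code{\link{CellTypeReference}}.
#' @param panel Named list cell type -> marker gene ids; every panel must
#'   be non-empty.
#' @param minSignal Detection floor (default 0).
#' @return List with a per-marker \code{table} (gene, panel type, class,
#'   status) and the \code{fraction_correct} among informative markers.
#' @export
validateMarkers <- function(reference, panel, minSignal = 0) {
    stopifnot(is(reference, "CellTypeReference"), length(panel) > 0)
    if (any(!lengths(panel)))
        stop("every cell type's marker panel must be non-empty")
    sig <- refSignal(reference)
    cls <- refClass(reference)
    rows <- do.call(rbind, lapply(names(panel), function(ct) {
        data.frame(gene_id = panel[[ct]], panel_type = ct)
    }))
    miss <- setdiff(rows$gene_id, rownames(sig))
    if (length(miss))
        stop("markers absent from reference: ", paste(miss, collapse = ", "))
    uninf <- apply(sig[rows$gene_id, , drop = FALSE], 1L,
                   function(v) all(v <= minSignal))
    rows$class <- unname(cls[rows$gene_id])
    rows$status <- ifelse(uninf, "non-informative",
                          ifelse(rows$class == rows$panel_type,
                                 "correct", "mismatch"))
    inf <- rows$status != "non-informative"
    list(table = rows,
         fraction_correct = if (any(inf))
             mean(rows$status[inf] == "correct") else NA_real_)
}

#' Classify a gene list by cell-type enrichment
#'
#' Labels every input gene with its reference enrichment class; genes
#' absent from the reference are labeled Unclassified and flagged missing.
#' Per-class counts always sum to the list length.
#'
#' @param genes Character vector of gene ids.
#' @param reference A \code{\link{CellTypeReference}}.
#' @return List with \code{table} (gene_id, class, missing) and
#'   \code{counts} (named vector over classes).
#' @export
annotateDegList <- function(genes, reference) {
    stopifnot(is(reference, "CellTypeReference"))
    cls <- refClass(reference)
    lab <- unname(cls[genes])
    missing <- is.na(lab)
    lab[missing] <- .UNCLASSIFIED
    tab <- data.frame(gene_id = genes, class = lab, missing = missing)
    counts <- table(factor(lab, levels = c(.CELL_TYPES, .UNCLASSIFIED)))
    list(table = tab, counts = c(counts))
}
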