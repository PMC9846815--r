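#' @import methods
#' @importFrom stats median p.adjust pnorm pt phyper rlnorm runif var
#'   setNames ave t.test
#' @importFrom utils head
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData colData
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @useDynLib mascot, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.CELL_TYPES <- c("motor_neuron", "neuron", "astrocyte", "microglia",
                 "oligodendrocyte")
.UNCLASSIFIED <- "Unclassified"

#' Cell types covered by the integrated reference
#'
#' The five major CNS cell types the reference and the simulator model:
#' motor neurons, (other) neurons, astrocytes, microglia and
#' oligodendrocytes.
#'
#' @return Character vector of cell-type labels.
#' @export
#' @examples
#' cellTypes()
cellTypes <- function() .CELL_TYPES

# ---------------------------------------------------------------------------
# ProbePairSet: probe-pair level intensities (PM/MM) for one chip design
# ---------------------------------------------------------------------------

#' @rdname ProbePairSet
#' @export
setClass("ProbePairSet", contains = "SummarizedExperiment")

setValidity("ProbePairSet", function(object) {
    msg <- character()
    if (!all(c("pm", "mm") %in% assayNames(object)))
        msg <- c(msg, "assays 'pm' and 'mm' are required")
    rd <- rowData(object)
    if (!all(c("probeset_id", "pair_index") %in% colnames(rd)))
        msg <- c(msg, "rowData must contain probeset_id and pair_index")
    else if (anyDuplicated(paste(rd$probeset_id, rd$pair_index)))
        msg <- c(msg, "duplicated (probeset_id, pair_index) entries")
    if ("pm" %in% assayNames(object)) {
        rng <- suppressWarnings(range(assay(object, "pm")))
        if (!all(is.finite(rng)) || rng[1] <= 0)
            msg <- c(msg, "pm intensities must be finite and > 0")
    }
    if ("mm" %in% assayNames(object)) {
        rng <- suppressWarnings(range(assay(object, "mm")))
        if (!all(is.finite(rng)) || rng[1] < 0)
            msg <- c(msg, "mm intensities must be finite and >= 0")
    }
    if (length(msg)) msg else TRUE
})

#' Probe-pair level intensity container
#'
#' A \linkS4class{SummarizedExperiment} whose rows are PM/MM probe pairs.
#' Assay \code{"pm"} holds perfect-match and \code{"mm"} mismatch
#' intensities; \code{rowData} records the probeset each pair belongs to and
#' its pair index within the probeset.
#'
#' @param pm,mm Numeric matrices (probe pairs x samples); \code{pm} strictly
#'   positive, \code{mm} non-negative.
#' @param probesetId Character vector, one probeset id per probe pair.
#' @param pairIndex Integer vector of within-probeset pair indices; computed
#'   from ordering if omitted.
#'
#' @return A \code{ProbePairSet}.
#' @export
#' @examples
#' pm <- matrix(c(100, 200, 300, 400), 2, 2,
#'              dimnames = list(NULL, c("s1", "s2")))
#' mm <- pm * 0.2
#' ProbePairSet(pm, mm, probesetId = c("ps1", "ps1"))
ProbePairSet <- function(pm, mm, probesetId, pairIndex = NULL) {
    pm <- as.matrix(pm); mm <- as.matrix(mm)
    stopifnot(identical(dim(pm), dim(mm)), length(probesetId) == nrow(pm))
    rownames(pm) <- rownames(mm) <- NULL
    if (is.null(pairIndex)) {
        pairIndex <- stats::ave(seq_along(probesetId), probesetId,
                                FUN = seq_along)
    }
    se <- SummarizedExperiment(
        assays = list(pm = pm, mm = mm),
        rowData = DataFrame(probeset_id = as.character(probesetId),
                            pair_index = as.integer(pairIndex)))
    new("ProbePairSet", se)
}

#' @rdname ProbePairSet
#' @param object,x A \code{ProbePairSet}.
#' @export
setMethod("show", "ProbePairSet", function(object) {
    cat(sprintf("ProbePairSet: %d probe pairs, %d probesets, %d samples\n",
                nrow(object),
                length(unique(rowData(object)$probeset_id)),
                ncol(object)))
})

#' @rdname ProbePairSet
#' @export
pmIntensity <- function(x) assay(x, "pm")

#' @rdname ProbePairSet
#' @export
mmIntensity <- function(x) assay(x, "mm")

#' @rdname ProbePairSet
#' @export
probesetIds <- function(x) rowData(x)$probeset_id

# ---------------------------------------------------------------------------
# MAS5Set: probeset-level signals + detection results
# ---------------------------------------------------------------------------

#' @rdname MAS5Set
#' @export
setClass("MAS5Set", contains = "SummarizedExperiment")

setValidity("MAS5Set", function(object) {
    msg <- character()
    need <- c("signal", "detection_p", "call")
    if (!all(need %in% assayNames(object)))
        msg <- c(msg, paste("assays required:", paste(need, collapse = ", ")))
    else {
        srng <- suppressWarnings(range(assay(object, "signal")))
        prng <- suppressWarnings(range(assay(object, "detection_p")))
        cl <- assay(object, "call")
        if (!all(is.finite(srng)) || srng[1] < 0)
            msg <- c(msg, "signals must be finite and >= 0")
        if (!all(is.finite(prng)) || prng[1] < 0 || prng[2] > 1)
            msg <- c(msg, "detection p-values must lie in [0, 1]")
        if (!all(cl == "P" | cl == "M" | cl == "A"))
            msg <- c(msg, "calls must be P, M or A")
    }
    if (is.null(metadata(object)$scale_factors))
        msg <- c(msg, "metadata$scale_factors is required")
    if (length(msg)) msg else TRUE
})

#' MAS5-style expression container
#'
#' Probeset x sample results of MAS5-style normalization: linear-scale
#' signals, detection p-values and Present/Marginal/Absent calls, with the
#' per-sample global scale factors in \code{metadata(x)$scale_factors}.
#' Constructed by \code{\link{mas5Normalize}}.
#'
#' @param signal,detectionP,call Probeset x sample matrices.
#' @param scaleFactors Named numeric vector, one scale factor per sample.
#' @param params The parameter list used (see \code{\link{mas5Params}}).
#' @return A \code{MAS5Set}.
#' @export
MAS5Set <- function(signal, detectionP, call, scaleFactors, params = list()) {
    se <- SummarizedExperiment(
        assays = list(signal = signal, detection_p = detectionP, call = call))
    metadata(se)$scale_factors <- scaleFactors
    metadata(se)$params <- params
    new("MAS5Set", se)
}

#' @rdname MAS5Set
#' @param object,x A \code{MAS5Set}.
#' @export
setMethod("show", "MAS5Set", function(object) {
    cat(sprintf("MAS5Set: %d probesets x %d samples\n",
                nrow(object), ncol(object)))
    cl <- assay(object, "call")
    tab <- table(factor(cl, levels = c("P", "M", "A")))
    cat("  calls:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
    cat("  scale factors:",
        paste(signif(metadata(object)$scale_factors, 4), collapse = " "), "\n")
})

#' @rdname MAS5Set
#' @export
exprSignal <- function(x) assay(x, "signal")

#' @rdname MAS5Set
#' @export
detectionP <- function(x) assay(x, "detection_p")

#' @rdname MAS5Set
#' @export
detectionCalls <- function(x) assay(x, "call")

#' @rdname MAS5Set
#' @export
scaleFactors <- function(x) metadata(x)$scale_factors

# ---------------------------------------------------------------------------
# CellTypeReference: integrated cell-type-specific transcriptome
# ---------------------------------------------------------------------------

#' @rdname CellTypeReference
#' @export
setClass("CellTypeReference", contains = "SummarizedExperiment")

setValidity("CellTypeReference", function(object) {
    msg <- character()
    if (!"mean_signal" %in% assayNames(object))
        msg <- c(msg, "assay 'mean_signal' is required")
    else if (any(assay(object, "mean_signal") < 0))
        msg <- c(msg, "reference signals must be >= 0")
    if (!"enrichment_class" %in% colnames(rowData(object)))
        msg <- c(msg, "rowData$enrichment_class is required")
    else {
        cl <- rowData(object)$enrichment_class
        if (!all(cl %in% c(.CELL_TYPES, .UNCLASSIFIED)))
            msg <- c(msg, "invalid enrichment class label")
    }
    if (is.null(metadata(object)$enrichment_factor))
        msg <- c(msg, "metadata$enrichment_factor is required")
    if (length(msg)) msg else TRUE
})

#' Integrated cell-type-specific expression reference
#'
#' A gene x cell-type table of mean MAS5-scaled signals together with each
#' gene's cell-type enrichment class: the label of the cell type whose
#' signal is at least \code{enrichment_factor} times every other type's
#' signal, or \code{"Unclassified"}. Built by \code{\link{buildReference}}.
#'
#' @param meanSignal Gene x cell-type numeric matrix; columns must be the
#'   five labels of \code{\link{cellTypes}}.
#' @param factor Enrichment ratio used for classification (default 4).
#' @return A \code{CellTypeReference}.
#' @export
CellTypeReference <- function(meanSignal, factor = 4) {
    meanSignal <- as.matrix(meanSignal)
    stopifnot(identical(colnames(meanSignal), .CELL_TYPES))
    cls <- apply(meanSignal, 1L, classifyEnrichment, factor = factor)
    se <- SummarizedExperiment(
        assays = list(mean_signal = meanSignal),
        rowData = DataFrame(enrichment_class = unname(cls)))
    metadata(se)$enrichment_factor <- factor
    new("CellTypeReference", se)
}

#' @rdname CellTypeReference
#' @param object,x A \code{CellTypeReference}.
#' @export
setMethod("show", "CellTypeReference", function(object) {
    cat(sprintf("CellTypeReference: %d genes x %d cell types (factor %g)\n",
                nrow(object), ncol(object),
                metadata(object)$enrichment_factor))
    print(table(factor(refClass(object), levels = c(.CELL_TYPES, .UNCLASSIFIED))))
})

#' @rdname CellTypeReference
#' @export
refSignal <- function(x) assay(x, "mean_signal")

#' @rdname CellTypeReference
#' @export
refClass <- function(x) {
    setNames(rowData(x)$enrichment_class, rownames(x))
}

# ---------------------------------------------------------------------------
# SyntheticTruth: planted ground truth for simulated datasets
# ---------------------------------------------------------------------------

#' @rdname SyntheticTruth
#' @export
setClass("SyntheticTruth", representation(
    plantedDeg = "character",
    plantedClass = "character",
    plantedEctopic = "data.frame",
    compositions = "list",
    noise = "list",
    seed = "integer"))

setValidity("SyntheticTruth", function(object) {
    msg <- character()
    if (!all(object@plantedDeg %in% names(object@plantedClass)))
        msg <- c(msg, "planted DEGs must be a subset of the gene universe")
    ec <- object@plantedEctopic
    if (nrow(ec)) {
        if (!all(c("gene_id", "cell_type") %in% colnames(ec)))
            msg <- c(msg, "plantedEctopic needs gene_id and cell_type columns")
        else {
            home <- object@plantedClass[ec$gene_id]
            if (any(is.na(home)) || any(home == ec$cell_type))
                msg <- c(msg,
                    "ectopic genes must have a planted class differing from the host cell type")
        }
    }
    if (length(msg)) msg else TRUE
})

#' Planted ground truth for a synthetic study
#'
#' Records everything the simulator planted: which genes carry disease
#' effects, each gene's cell-type enrichment class, ectopic inductions
#' (gene, host cell type), the tissue composition vectors, noise parameters
#' and the master seed. Serializes losslessly to JSON via
#' \code{\link{writeTruth}} / \code{\link{readTruth}}.
#'
#' @param plantedDeg Character vector of planted DEG gene ids.
#' @param plantedClass Named character vector gene -> class label.
#' @param plantedEctopic data.frame with columns gene_id, cell_type.
#' @param compositions List of named composition weight vectors.
#' @param noise List of noise parameters.
#' @param seed Integer master seed.
#' @return A \code{SyntheticTruth}.
#' @export
SyntheticTruth <- function(plantedDeg = character(),
                           plantedClass = character(),
                           plantedEctopic = data.frame(
                               gene_id = character(),
                               cell_type = character()),
                           compositions = list(),
                           noise = list(),
                           seed = NA_integer_) {
    # compositions kept as plain named numeric vectors (JSON-stable)
    compositions <- lapply(compositions, function(w)
        if (is.numeric(w)) unlist(as.list(w)) else w)
    new("SyntheticTruth",
        plantedDeg = as.character(plantedDeg),
        plantedClass = plantedClass,
        plantedEctopic = plantedEctopic,
        compositions = compositions,
        noise = noise,
        seed = as.integer(seed))
}

#' @rdname SyntheticTruth
#' @param object A \code{SyntheticTruth}.
#' @export
setMethod("show", "SyntheticTruth", function(object) {
    cat(sprintf(
        "SyntheticTruth: %d genes, %d planted DEGs, %d ectopic, seed %s\n",
        length(object@plantedClass), length(object@plantedDeg),
        nrow(object@plantedEctopic), object@seed))
})

#' @rdname SyntheticTruth
#' @param x A \code{SyntheticTruth}.
#' @export
plantedDeg <- function(x) x@plantedDeg

#' @rdname SyntheticTruth
#' @export
plantedClass <- function(x) x@plantedClass

#' @rdname SyntheticTruth
#' @export
plantedEctopic <- function(x) x@plantedEctopic
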