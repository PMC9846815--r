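# Synthetic probe-level data with planted ground truth.
#
# The generator emulates the structure of a mixed-tissue CNS microarray
# study: five cell-type expression profiles, spinal-cord samples whose cell
# composition can shift with disease (motor-neuron loss, gliosis), planted
# per-gene per-cell-type disease fold changes including ectopic inductions,
# isolated cell-type samples with cross-cell-type contamination, and
# probe-level multiplicative log-normal noise on top of a flat additive
# background.

.lognoise <- function(n, cv) {
    if (cv == 0) return(rep(1, n))
    s <- sqrt(log(1 + cv^2))
    rlnorm(n, meanlog = -s^2 / 2, sdlog = s)  # mean exactly 1
}

.substream <- function(seed, k) {
    # deterministic derived seed, kept well inside 32-bit range
    (as.integer(seed) %% 2146001L) * 1000L + as.integer(k)
}

#' Generate cell-type expression profiles with planted enrichment classes
#'
#' Draws a linear-scale base abundance for every gene in every cell type.
#' A chosen fraction of genes is planted as cell-type enriched: one cell
#' type is set to \code{enrichmentFactor} times the maximum of the other
#' four. The remaining genes have all pairwise ratios below 1.9, so they
#' can never satisfy a fourfold enrichment rule.
#'
#' @param nGenes Number of genes (>= 10).
#' @param enrichedFraction Fraction of genes planted as enriched.
#' @param enrichmentFactor Ratio used for planting (>= 1; default 5).
#' @param seed Integer seed.
#' @return List with \code{profiles} (gene x cell-type matrix) and
#'   \code{plantedClass} (named character vector; \code{"Unclassified"} for
#'   unenriched genes).
#' @export
#' @examples
#' p <- generateCellTypeProfiles(100, enrichedFraction = 0.2, seed = 1)
#' table(p$plantedClass)
generateCellTypeProfiles <- function(nGenes, enrichedFraction = 0.2,
                                     enrichmentFactor = 5, seed = 1) {
    if (nGenes < 10) stop("nGenes must be >= 10")
    if (enrichedFraction < 0 || enrichedFraction > 1)
        stop("enrichedFraction must lie in [0, 1]")
    if (enrichmentFactor < 1) stop("enrichmentFactor must be >= 1")
    set.seed(seed)
    genes <- sprintf("g%05d", seq_len(nGenes))
    base <- rlnorm(nGenes, meanlog = log(200), sdlog = 1)
    prof <- base * matrix(runif(nGenes * 5L, 1, 1.9), nGenes, 5L)
    dimnames(prof) <- list(genes, .CELL_TYPES)
    cls <- setNames(rep(.UNCLASSIFIED, nGenes), genes)
    nEnr <- round(enrichedFraction * nGenes)
    if (nEnr > 0) {
        idx <- sample.int(nGenes, nEnr)
        types <- sample(rep_len(.CELL_TYPES, nEnr))
        for (i in seq_len(nEnr)) {
            g <- idx[i]; ct <- types[i]
            others <- base[g] * runif(4L, 0.5, 1)
            prof[g, ] <- NA_real_
            prof[g, setdiff(.CELL_TYPES, ct)] <- others
            prof[g, ct] <- enrichmentFactor * max(others)
        }
        cls[idx] <- types
    }
    list(profiles = prof, plantedClass = cls)
}

#' Tissue cell-composition vector
#'
#' Named weight vector over the five cell types, summing to one, tagged
#' with the condition it describes. \code{defaultCompositions()} returns
#' the control/disease pair used throughout: disease lowers the
#' motor-neuron weight and raises astrocyte and microglia weights, the
#' composition signature of motor-neuron loss with astro-/microgliosis.
#'
#' @param weights Named numeric vector over \code{\link{cellTypes}()};
#'   non-negative, summing to 1 within 1e-9.
#' @param condition \code{"control"} or \code{"disease"}.
#' @return The validated weight vector with a \code{condition} attribute.
#' @export
#' @examples
#' defaultCompositions()$control
compositionVector <- function(weights, condition = c("control", "disease")) {
    condition <- match.arg(condition)
    stopifnot(identical(sort(names(weights)), sort(.CELL_TYPES)))
    weights <- weights[.CELL_TYPES]
    if (any(weights < 0)) stop("composition weights must be >= 0")
    if (abs(sum(weights) - 1) > 1e-9)
        stop("composition weights must sum to 1 (tolerance 1e-9)")
    structure(weights, condition = condition)
}

#' @rdname compositionVector
#' @export
defaultCompositions <- function() {
    list(
        control = compositionVector(
            c(motor_neuron = 0.10, neuron = 0.30, astrocyte = 0.25,
              microglia = 0.15, oligodendrocyte = 0.20), "control"),
        disease = compositionVector(
            c(motor_neuron = 0.04, neuron = 0.26, astrocyte = 0.32,
              microglia = 0.23, oligodendrocyte = 0.15), "disease"))
}

.checkDiseaseShift <- function(control, disease) {
    ok <- disease["motor_neuron"] < control["motor_neuron"] &&
        disease["astrocyte"] > control["astrocyte"] &&
        disease["microglia"] > control["microglia"]
    if (!ok)
        stop("disease composition must lower motor_neuron and raise ",
             "astrocyte and microglia weights relative to control")
    invisible(TRUE)
}

#' Disease effect table
#'
#' Per-gene per-cell-type multiplicative disease fold changes. An effect
#' marked ectopic is an induction in a cell type other than the gene's
#' planted enrichment class.
#'
#' @param gene_id,cell_type,fold_change Parallel vectors; fold changes must
#'   be > 0.
#' @param ectopic Logical vector (default all FALSE).
#' @return data.frame with one row per (gene, cell type) effect.
#' @export
diseaseEffects <- function(gene_id, cell_type, fold_change,
                           ectopic = FALSE) {
    stopifnot(all(fold_change > 0), all(cell_type %in% .CELL_TYPES))
    data.frame(gene_id = as.character(gene_id),
               cell_type = as.character(cell_type),
               fold_change = as.numeric(fold_change),
               ectopic = rep_len(as.logical(ectopic), length(gene_id)))
}

.effectMatrix <- function(genes, effects) {
    fc <- matrix(1, length(genes), 5L, dimnames = list(genes, .CELL_TYPES))
    if (!is.null(effects) && nrow(effects)) {
        miss <- setdiff(effects$gene_id, genes)
        if (length(miss)) stop("effects reference unknown genes: ",
                               paste(head(miss), collapse = ", "))
        fc[cbind(effects$gene_id, effects$cell_type)] <- effects$fold_change
    }
    fc
}

#' Expected tissue abundance of a cell mixture
#'
#' Closed-form per-gene abundance of a mixed sample:
#' \eqn{\sum_c w_c \cdot profile_{g,c} \cdot effect_{g,c}}. This is the
#' noise-free expectation the simulator perturbs, exposed for use as an
#' oracle.
#'
#' @param profiles Gene x cell-type matrix.
#' @param weights Named mixture weights over cell types.
#' @param effects Optional \code{\link{diseaseEffects}} table.
#' @return Named per-gene abundance vector.
#' @export
mixtureAbundance <- function(profiles, weights, effects = NULL) {
    fc <- .effectMatrix(rownames(profiles), effects)
    drop((profiles * fc) %*% weights[.CELL_TYPES])
}

#' Chip layout with frozen probe affinities
#'
#' Assigns each gene one probeset (a small fraction get a second probeset,
#' emulating transcripts interrogated by multiple probesets) and draws a
#' per-probe-pair affinity once from a log-normal with sdlog
#' \code{affinitySd}. Affinities are frozen in the layout so probeset
#' summarization faces heterogeneous probes and control/disease samples
#' simulated from the same layout are comparable.
#'
#' @param genes Character vector of gene ids.
#' @param probesPerSet Probe pairs per probeset (4 to 20; default 11).
#' @param dupFraction Fraction of genes with a second probeset.
#' @param affinitySd sdlog of the affinity log-normal (default 0.3).
#' @param seed Integer seed.
#' @return data.frame with columns probeset_id, gene_id, pair_index,
#'   affinity.
#' @export
makeChipLayout <- function(genes, probesPerSet = 11, dupFraction = 0.05,
                           affinitySd = 0.3, seed = 1) {
    if (probesPerSet < 4 || probesPerSet > 20)
        stop("probesPerSet must lie between 4 and 20")
    set.seed(seed)
    nDup <- round(dupFraction * length(genes))
    dup <- if (nDup > 0) sample(genes, nDup) else character()
    dupPs <- if (length(dup)) paste0(dup, "_x_at") else character()
    ps <- data.frame(
        probeset_id = c(paste0(genes, "_at"), dupPs),
        gene_id = c(genes, dup))
    ps <- ps[order(ps$gene_id, ps$probeset_id), ]
    layout <- data.frame(
        probeset_id = rep(ps$probeset_id, each = probesPerSet),
        gene_id = rep(ps$gene_id, each = probesPerSet),
        pair_index = rep(seq_len(probesPerSet), nrow(ps)),
        affinity = rlnorm(nrow(ps) * probesPerSet, 0, affinitySd))
    rownames(layout) <- NULL
    layout
}

.simulateProbeMatrices <- function(abundance, layout, nReplicates, noise,
                                   crossHyb, label, seed) {
    set.seed(seed)
    cv <- noise$cv %||% 0.15
    bg <- noise$background %||% 50
    specific <- abundance[layout$gene_id] * layout$affinity
    n <- nrow(layout)
    pm <- specific * matrix(.lognoise(n * nReplicates, cv), n) + bg
    mm <- crossHyb * specific *
        matrix(.lognoise(n * nReplicates, cv), n) + bg
    colnames(pm) <- colnames(mm) <- paste0(label, "_", seq_len(nReplicates))
    list(pm = pm, mm = mm)
}

.simulateProbePairs <- function(abundance, layout, nReplicates, noise,
                                crossHyb, label, seed) {
    m <- .simulateProbeMatrices(abundance, layout, nReplicates, noise,
                                crossHyb, label, seed)
    ProbePairSet(m$pm, m$mm, probesetId = layout$probeset_id,
                 pairIndex = layout$pair_index)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate mixed-tissue probe-level samples
#'
#' Per-gene tissue abundance is the composition-weighted sum of cell-type
#' profiles, with disease fold changes applied per cell type when the
#' composition's condition is \code{"disease"}. PM intensities are
#' abundance x frozen probe affinity x log-normal noise plus a flat
#' additive background; MM carries a \code{crossHyb} fraction of the
#' specific part plus the same background.
#'
#' @param profiles Gene x cell-type matrix
#'   (\code{\link{generateCellTypeProfiles}}).
#' @param composition A \code{\link{compositionVector}}.
#' @param effects Optional \code{\link{diseaseEffects}} table (applied only
#'   for disease compositions).
#' @param nReplicates Number of arrays (>= 2; default 3).
#' @param noise List with \code{cv} (coefficient of variation of the
#'   multiplicative log-normal noise) and \code{background} (flat additive
#'   mean).
#' @param crossHyb Fraction of the specific signal leaking into MM
#'   (default 0.2).
#' @param layout Chip layout from \code{\link{makeChipLayout}}; created
#'   when omitted. All datasets that will be compared or combined must
#'   share one layout (one array platform), so pass the same layout to
#'   paired control/disease calls and to every cell-type dataset of an
#'   integrated reference.
#' @param probesPerSet Probe pairs per probeset when a layout is created
#'   here (default 11).
#' @param label Sample name prefix.
#' @param seed Integer seed.
#' @return List with \code{data} (a \code{\link{ProbePairSet}}) and
#'   \code{layout}.
#' @export
generateTissueSamples <- function(profiles, composition, effects = NULL,
                                  nReplicates = 3,
                                  noise = list(cv = 0.15, background = 50),
                                  crossHyb = 0.2, layout = NULL,
                                  probesPerSet = 11,
                                  label = attr(composition, "condition"),
                                  seed = 1) {
    if (nReplicates < 2) stop("nReplicates must be >= 2")
    composition <- compositionVector(composition,
                                     attr(composition, "condition") %||% "control")
    if (is.null(layout))
        layout <- makeChipLayout(rownames(profiles),
                                 probesPerSet = probesPerSet,
                                 seed = .substream(seed, 1))
    eff <- if (identical(attr(composition, "condition"), "disease"))
        effects else NULL
    abundance <- mixtureAbundance(profiles, composition, eff)
    data <- .simulateProbePairs(abundance, layout, nReplicates, noise,
                                crossHyb, label, .substream(seed, 2))
    list(data = data, layout = layout)
}

#' Simulate isolated cell-type probe-level samples
#'
#' Emulates cell-type datasets isolated by capture or sorting, which carry
#' some contamination from adjacent cell types: the sample abundance is
#' \code{(1 - f)} times the target cell type's profile plus \code{f} spread
#' uniformly over the other four types. Disease fold changes are applied
#' per cell type before mixing, so foreign-type inductions leak into the
#' dataset proportionally to the contamination.
#'
#' @inheritParams generateTissueSamples
#' @param targetCellType One of \code{\link{cellTypes}()}.
#' @param contaminationFraction Fraction in [0, 0.5); at 0.5 the target
#'   would no longer dominate and the call is rejected.
#' @param condition \code{"control"} or \code{"disease"}; effects apply
#'   only in disease.
#' @return List with \code{data} and \code{layout}, as
#'   \code{\link{generateTissueSamples}}.
#' @export
generateIsolatedCellTypeSamples <- function(profiles, targetCellType,
                                            contaminationFraction = 0.1,
                                            effects = NULL,
                                            condition = c("control", "disease"),
                                            nReplicates = 3,
                                            noise = list(cv = 0.15,
                                                         background = 50),
                                            crossHyb = 0.2, layout = NULL,
                                            probesPerSet = 11,
                                            label = NULL, seed = 1) {
    condition <- match.arg(condition)
    stopifnot(targetCellType %in% .CELL_TYPES)
    if (contaminationFraction < 0 || contaminationFraction >= 0.5)
        stop("contaminationFraction must lie in [0, 0.5)")
    if (nReplicates < 2) stop("nReplicates must be >= 2")
    w <- setNames(rep(contaminationFraction / 4, 5L), .CELL_TYPES)
    w[targetCellType] <- 1 - contaminationFraction
    if (is.null(layout))
        layout <- makeChipLayout(rownames(profiles),
                                 probesPerSet = probesPerSet,
                                 seed = .substream(seed, 1))
    eff <- if (condition == "disease") effects else NULL
    abundance <- mixtureAbundance(profiles, w, eff)
    if (is.null(label)) label <- paste0(targetCellType, "_", condition)
    data <- .simulateProbePairs(abundance, layout, nReplicates, noise,
                                crossHyb, label, .substream(seed, 2))
    list(data = data, layout = layout)
}

#' Simulate a complete three-comparison tissue study
#'
#' Builds the probe-level datasets for three mutant-vs-control comparisons
#' (3 vs 3 arrays each by default) over a shared chip layout, with a chosen
#' number of planted differentially expressed genes. Planted effects are
#' two-sided: half up-regulated and half down-regulated, with fold-change
#' magnitudes drawn log-uniformly from \code{fcRange} and applied in every
#' cell type, so the planted tissue-level fold change equals the drawn
#' factor. Mutant and control samples share the control composition, so
#' planted effects are the only systematic signal.
#'
#' @param nGenes Number of genes.
#' @param nDeg Number of planted DEGs (0 for a null study).
#' @param fcRange Magnitude range of planted fold changes (default
#'   c(2.5, 8)).
#' @param nComparisons Number of mutant lines (default 3).
#' @param nReplicates Arrays per group (default 3).
#' @param noise,crossHyb,probesPerSet,dupFraction As in the generators.
#' @param enrichedFraction,enrichmentFactor Passed to
#'   \code{\link{generateCellTypeProfiles}} when \code{profiles} is not
#'   supplied.
#' @param profiles,plantedClass Optional pre-generated cell-type profiles
#'   and class assignment (both from
#'   \code{\link{generateCellTypeProfiles}}).
#' @param degClassFractions Optional named vector of fractions, e.g.
#'   \code{c(microglia = 0.55)}: that share of planted DEGs is drawn from
#'   genes of the given planted class, the rest from the whole universe.
#' @param seed Master seed; all substreams derive from it.
#' @return List with \code{comparisons} (each a list with \code{data}, a
#'   \code{\link{ProbePairSet}} holding the comparison's six arrays, and
#'   the \code{mutant} / \code{control} sample names), \code{layout},
#'   \code{annotation} (probeset -> gene data.frame), \code{profiles} and
#'   \code{truth} (a \code{\link{SyntheticTruth}}).
#' @export
simulateTissueStudy <- function(nGenes = 2000, nDeg = 40,
                                fcRange = c(2.5, 8), nComparisons = 3,
                                nReplicates = 3,
                                noise = list(cv = 0.15, background = 50),
                                crossHyb = 0.2, probesPerSet = 11,
                                dupFraction = 0.05,
                                enrichedFraction = 0.2,
                                enrichmentFactor = 5,
                                profiles = NULL, plantedClass = NULL,
                                degClassFractions = NULL, seed = 1) {
    if (is.null(profiles)) {
        prof <- generateCellTypeProfiles(nGenes,
                                         enrichedFraction = enrichedFraction,
                                         enrichmentFactor = enrichmentFactor,
                                         seed = .substream(seed, 11))
    } else {
        stopifnot(!is.null(plantedClass))
        prof <- list(profiles = profiles, plantedClass = plantedClass)
    }
    genes <- rownames(prof$profiles)
    layout <- makeChipLayout(genes, probesPerSet = probesPerSet,
                             dupFraction = dupFraction,
                             seed = .substream(seed, 12))
    set.seed(.substream(seed, 13))
    degGenes <- character()
    if (nDeg > 0) {
        if (!is.null(degClassFractions)) {
            for (ct in names(degClassFractions)) {
                pool <- genes[prof$plantedClass == ct]
                take <- min(round(degClassFractions[[ct]] * nDeg),
                            length(pool))
                degGenes <- c(degGenes, sample(pool, take))
            }
        }
        rest <- setdiff(genes, degGenes)
        degGenes <- c(degGenes, sample(rest, nDeg - length(degGenes)))
    }
    fcMag <- exp(runif(nDeg, log(fcRange[1]), log(fcRange[2])))
    up <- rep(c(TRUE, FALSE), length.out = nDeg)
    fcs <- ifelse(up, fcMag, 1 / fcMag)
    effects <- if (nDeg > 0) {
        diseaseEffects(gene_id = rep(degGenes, each = 5L),
                       cell_type = rep(.CELL_TYPES, nDeg),
                       fold_change = rep(fcs, each = 5L))
    } else NULL
    comp <- defaultCompositions()$control
    compMut <- compositionVector(unclass(comp), "disease")
    abundCtl <- mixtureAbundance(prof$profiles, comp, NULL)
    abundMut <- mixtureAbundance(prof$profiles, compMut, effects)
    comparisons <- lapply(seq_len(nComparisons), function(i) {
        ctl <- .simulateProbeMatrices(abundCtl, layout, nReplicates, noise,
                                      crossHyb, sprintf("c%d_ctl", i),
                                      .substream(seed, 20 + 2 * i))
        mut <- .simulateProbeMatrices(abundMut, layout, nReplicates, noise,
                                      crossHyb, sprintf("c%d_mut", i),
                                      .substream(seed, 21 + 2 * i))
        list(data = ProbePairSet(cbind(mut$pm, ctl$pm),
                                 cbind(mut$mm, ctl$mm),
                                 probesetId = layout$probeset_id,
                                 pairIndex = layout$pair_index),
             mutant = colnames(mut$pm), control = colnames(ctl$pm))
    })
    names(comparisons) <- paste0("comparison", seq_len(nComparisons))
    annotation <- unique(layout[, c("probeset_id", "gene_id")])
    truth <- SyntheticTruth(
        plantedDeg = degGenes,
        plantedClass = prof$plantedClass,
        compositions = list(control = unclass(comp),
                            mutant = unclass(compMut)),
        noise = c(noise, list(crossHyb = crossHyb, fcRange = fcRange)),
        seed = seed)
    list(comparisons = comparisons, layout = layout,
         annotation = annotation, profiles = prof$profiles, truth = truth)
}
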