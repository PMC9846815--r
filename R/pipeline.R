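# End-to-end orchestration: simulate -> normalize -> DEG extraction ->
# integrated reference -> classification -> disease cross-reference ->
# over-representation, with every stage output written to a run directory
# and a truth-vs-result report when ground truth exists.

#' Pipeline run configuration
#'
#' Validated bundle of simulation parameters, engine constants and
#' analysis thresholds for \code{\link{runPipeline}}.
#'
#' @param nGenes,nDeg,fcRange,nComparisons,nReplicates,probesPerSet,dupFraction
#'   Study design passed to \code{\link{simulateTissueStudy}}.
#' @param cv,background,crossHyb Probe-level noise model.
#' @param enrichedFraction,enrichmentFactor Planted cell-type enrichment.
#' @param degMicrogliaFraction Share of planted DEGs drawn from
#'   microglia-class genes (default 0.55, the microglia-dominant signature
#'   of ALS spinal cord).
#' @param contamination Contamination fraction of the disease-specific
#'   isolated cell-type datasets (capture-microdissection-like).
#' @param referenceContamination Contamination of the high-purity sorted
#'   or immunopanned datasets the integrated reference is built from
#'   (default 0.01, i.e. 99 percent purity).
#' @param nEctopic,ectopicFold Number and strength of planted ectopic
#'   inductions (microglia-class genes induced in astrocytes).
#' @param mas5 Engine constants, see \code{\link{mas5Params}}.
#' @param fcThreshold,fdr,requireFdr,minPM,requireDirection DEG criteria.
#' @param classFactor Enrichment classifier ratio (default 4).
#' @param k,floorFc Ectopic-detection rule.
#' @param seed Master seed.
#' @return Named list of validated settings.
#' @export
pipelineConfig <- function(nGenes = 2000, nDeg = 40, fcRange = c(2.5, 8),
                           nComparisons = 3, nReplicates = 3,
                           probesPerSet = 11, dupFraction = 0.05,
                           cv = 0.15, background = 50, crossHyb = 0.2,
                           enrichedFraction = 0.2, enrichmentFactor = 5,
                           degMicrogliaFraction = 0.55,
                           contamination = 0.1,
                           referenceContamination = 0.01, nEctopic = 1,
                           ectopicFold = 50,
                           mas5 = mas5Params(),
                           fcThreshold = 2, fdr = 0.05,
                           requireFdr = FALSE, minPM = 3,
                           requireDirection = TRUE, classFactor = 4,
                           k = 3, floorFc = 10, seed = 1) {
    stopifnot(nGenes >= 10, nDeg >= 0, nDeg <= nGenes,
              length(fcRange) == 2, fcRange[1] > 1,
              nComparisons >= 2, nReplicates >= 2,
              cv >= 0, background >= 0, crossHyb >= 0,
              contamination >= 0, contamination < 0.5,
              referenceContamination >= 0, referenceContamination < 0.5,
              nEctopic >= 0, ectopicFold > 0,
              fcThreshold >= 1, fdr > 0, fdr < 1, classFactor >= 1,
              k > 0, floorFc > 0)
    as.list(environment())
}

.configHash <- function(config) {
    dump <- paste(deparse(config[order(names(config))]), collapse = "")
    substr(.md5string(dump), 1, 8)
}

.md5string <- function(s) {
    tmp <- tempfile()
    writeLines(s, tmp)
    on.exit(unlink(tmp))
    unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline on simulated data
#'
#' Simulates a three-comparison tissue study plus isolated cell-type
#' datasets from one master seed, then runs MAS5-style normalization, DEG
#' extraction with intersection and deduplication, reference building and
#' DEG classification, ectopic-expression cross-referencing in the
#' diseased astrocyte dataset, and over-representation of the planted
#' class categories — writing every stage's table under \code{outDir}.
#' Output filenames carry the seed and a config hash; the run is
#' deterministic given the seed.
#'
#' @param config See \code{\link{pipelineConfig}}.
#' @param outDir Output directory (created if needed).
#' @return Invisibly, a list with the \code{report} (recovery metrics,
#'   class counts, ectopic calls, enrichment table), stage results and
#'   output \code{files}.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = tempfile("run")) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    seed <- config$seed
    tag <- paste0("s", seed, "_", .configHash(config), "_")
    fp <- function(name) file.path(outDir, paste0(tag, name))
    files <- character()
    put <- function(name) { f <- fp(name); files <<- c(files, f); f }

    jsonlite::write_json(config[setdiff(names(config), "mas5")],
                         put("config.json"), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)

    noise <- list(cv = config$cv, background = config$background)

    ## --- simulate -------------------------------------------------------
    prof <- generateCellTypeProfiles(config$nGenes,
                                     enrichedFraction = config$enrichedFraction,
                                     enrichmentFactor = config$enrichmentFactor,
                                     seed = .substream(seed, 1))
    study <- simulateTissueStudy(
        nGenes = config$nGenes, nDeg = config$nDeg,
        fcRange = config$fcRange, nComparisons = config$nComparisons,
        nReplicates = config$nReplicates, noise = noise,
        crossHyb = config$crossHyb, probesPerSet = config$probesPerSet,
        dupFraction = config$dupFraction,
        profiles = prof$profiles, plantedClass = prof$plantedClass,
        degClassFractions = c(microglia = config$degMicrogliaFraction),
        seed = seed)
    genes <- rownames(prof$profiles)

    # isolated cell-type datasets: healthy for the reference, plus a
    # diseased/control astrocyte pair for the cross-reference stage
    mgGenes <- genes[prof$plantedClass == "microglia"]
    set.seed(.substream(seed, 3))
    ectopicGenes <- if (config$nEctopic > 0)
        sample(mgGenes, config$nEctopic) else character()
    mgMarkers <- head(setdiff(mgGenes, ectopicGenes), 3)
    set.seed(.substream(seed, 4))
    mgEffects <- diseaseEffects(
        gene_id = mgGenes, cell_type = "microglia",
        fold_change = exp(runif(length(mgGenes), log(0.6), log(8.5))))
    isoEffects <- rbind(
        mgEffects,
        if (length(ectopicGenes)) diseaseEffects(
            gene_id = ectopicGenes, cell_type = "astrocyte",
            fold_change = config$ectopicFold, ectopic = TRUE))

    isoHealthy <- lapply(setNames(nm = .CELL_TYPES), function(ct)
        generateIsolatedCellTypeSamples(
            prof$profiles, ct, config$referenceContamination, NULL,
            "control", config$nReplicates, noise, config$crossHyb,
            study$layout, seed = .substream(seed, 5 + match(ct, .CELL_TYPES))))
    astControl <- generateIsolatedCellTypeSamples(
        prof$profiles, "astrocyte", config$contamination, NULL,
        "control", config$nReplicates, noise, config$crossHyb,
        study$layout, label = "astrocyte_ctl", seed = .substream(seed, 30))
    astDisease <- generateIsolatedCellTypeSamples(
        prof$profiles, "astrocyte", config$contamination, isoEffects,
        "disease", config$nReplicates, noise, config$crossHyb,
        study$layout, label = "astrocyte_dis", seed = .substream(seed, 31))

    truth <- study$truth
    truth@plantedEctopic <- if (length(ectopicGenes))
        data.frame(gene_id = ectopicGenes, cell_type = "astrocyte")
    else data.frame(gene_id = character(), cell_type = character())
    validObject(truth)
    writeTruth(truth, put("truth.json"))
    writeChipLayoutTSV(study$layout, put("layout.tsv"))
    writeAnnotationTSV(study$annotation, put("annotation.tsv"))

    ## --- normalize ------------------------------------------------------
    norm <- lapply(study$comparisons, function(cmp)
        list(expr = mas5Normalize(cmp$data, config$mas5),
             mutant = cmp$mutant, control = cmp$control))
    for (i in seq_along(norm))
        writeExpressionTSV(norm[[i]]$expr,
                           put(sprintf("expr_comparison%d.tsv", i)))

    ## --- DEG extraction -------------------------------------------------
    degs <- extractDegs(norm, study$annotation,
                        fcThreshold = config$fcThreshold, fdr = config$fdr,
                        requireFdr = config$requireFdr, minPM = config$minPM,
                        requireDirection = config$requireDirection)
    .fwrite(degs$genes, put("degs.tsv"))

    ## --- integrated reference + classification --------------------------
    isoNorm <- lapply(isoHealthy, function(d) mas5Normalize(d$data, config$mas5))
    reference <- buildReference(isoNorm, study$annotation,
                                factor = config$classFactor)
    writeReferenceTSV(reference, put("reference.tsv"))
    classified <- annotateDegList(degs$genes$gene_id, reference)
    .fwrite(classified$table, put("deg_classes.tsv"))

    ## --- disease cross-reference ----------------------------------------
    astNorm <- mas5Normalize(astDisease$data, config$mas5)
    astCtlNorm <- mas5Normalize(astControl$data, config$mas5)
    fcTab <- diseaseFcTable(list(
        astrocyte_dis = cellTypeFoldChanges(astNorm, astCtlNorm,
                                            study$annotation)))
    panel <- list(microglia = mgMarkers)
    candidates <- rownames(fcTab)[refClass(reference)[rownames(fcTab)] ==
                                      "microglia"]
    candidates <- candidates[!is.na(candidates)]
    ectopic <- detectEctopic(candidates, fcTab, reference, panel,
                             "astrocyte_dis", "astrocyte",
                             k = config$k, floorFc = config$floorFc)
    .fwrite(ectopic, put("ectopic.tsv"))

    ## --- over-representation --------------------------------------------
    cm <- data.frame(gene_id = genes, category = unname(prof$plantedClass))
    cm <- cm[cm$category != .UNCLASSIFIED, ]
    enr <- if (nrow(degs$genes)) {
        overrepresentationTest(degs$genes$gene_id, cm,
                               referenceSize = config$nGenes)
    } else {
        data.frame(category = character(), reference_count = integer(),
                   observed = integer(), expected = numeric(),
                   fold_enrichment = numeric(), p_raw = numeric(),
                   q = numeric())
    }
    .fwrite(enr, put("enrichment.tsv"))

    ## --- truth-vs-result report -----------------------------------------
    recovered <- degs$genes$gene_id
    planted <- plantedDeg(truth)
    sens <- if (length(planted))
        mean(planted %in% recovered) else NA_real_
    fdp <- if (length(recovered))
        mean(!recovered %in% planted) else 0
    report <- list(
        seed = seed, config_hash = .configHash(config),
        n_entities = length(degs$entities),
        n_genes = nrow(degs$genes),
        deg_sensitivity = sens, deg_fdp = fdp,
        class_counts = as.list(classified$counts),
        ectopic_flagged = ectopic$gene_id[ectopic$flag],
        ectopic_true = ectopicGenes,
        enrichment = enr)
    jsonlite::write_json(report, put("report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(list(report = report, degs = degs, reference = reference,
                   classified = classified, ectopic = ectopic,
                   enrichment = enr, truth = truth, files = files,
                   dir = outDir))
}
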