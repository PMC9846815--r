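# Integrated cell-type reference and the fourfold enrichment classifier.

test_that("enrichment classifier applies the inclusive fourfold rule", {
    expect_equal(classifyEnrichment(
        c(motor_neuron = 100, neuron = 90, astrocyte = 80,
          microglia = 500, oligodendrocyte = 70)), "microglia")
    expect_equal(classifyEnrichment(
        c(motor_neuron = 100, neuron = 100, astrocyte = 300,
          microglia = 250, oligodendrocyte = 50)), "Unclassified")
    # boundary: exactly fourfold classifies ("at least" is inclusive)
    expect_equal(classifyEnrichment(
        c(motor_neuron = 0, neuron = 0, astrocyte = 0,
          microglia = 40, oligodendrocyte = 10)), "microglia")
    # runner-up zero, maximum positive: classify to the maximum
    expect_equal(classifyEnrichment(
        c(motor_neuron = 0, neuron = 0, astrocyte = 0,
          microglia = 7, oligodendrocyte = 0)), "microglia")
    expect_equal(classifyEnrichment(rep(0, 5)), "Unclassified")
    # tie at the maximum cannot be enriched
    expect_equal(classifyEnrichment(
        c(motor_neuron = 50, neuron = 50, astrocyte = 1,
          microglia = 2, oligodendrocyte = 3)), "Unclassified")
})

test_that("classification is gene-scale invariant but not type-rescale invariant", {
    set.seed(30)
    for (i in 1:25) {
        v <- setNames(runif(5, 0, 100), cellTypes())
        k <- runif(1, 0.01, 100)
        expect_equal(classifyEnrichment(v), classifyEnrichment(v * k))
    }
    # rescaling one cell type's column changes labels: a 5-fold microglial
    # gene stops classifying once the astrocyte axis is inflated 3-fold
    v <- c(motor_neuron = 10, neuron = 10, astrocyte = 20, microglia = 100,
           oligodendrocyte = 10)
    expect_equal(classifyEnrichment(v), "microglia")
    v2 <- v; v2["astrocyte"] <- v2["astrocyte"] * 3
    expect_equal(classifyEnrichment(v2), "Unclassified")
})

test_that("reference construction averages replicates and joins datasets", {
    genes <- paste0("g", 1:6)
    mats <- lapply(setNames(nm = cellTypes()), function(ct) {
        m <- matrix(seq_len(12), 6, 2,
                    dimnames = list(genes, paste0(ct, 1:2)))
        m * match(ct, cellTypes())
    })
    ref <- buildReference(mats)
    expect_equal(unname(refSignal(ref)[, "neuron"]),
                 rowMeans(mats$neuron)[genes], ignore_attr = TRUE)
    # two identical replicates: mean equals the replicate
    one <- lapply(mats, function(m) cbind(m[, 1], m[, 1]))
    ref1 <- buildReference(one)
    expect_equal(unname(refSignal(ref1)[, 1]), unname(mats[[1]][, 1]))
})

test_that("mismatched scaling targets are rejected", {
    st <- simulateTissueStudy(nGenes = 30, nDeg = 0, nComparisons = 2,
                              seed = 33, dupFraction = 0)
    m1 <- mas5Normalize(st$comparisons[[1]]$data)
    m2 <- mas5Normalize(st$comparisons[[2]]$data,
                        mas5Params(scaleTarget = 100))
    sets <- list(motor_neuron = m1, neuron = m2, astrocyte = m1,
                 microglia = m1, oligodendrocyte = m1)
    expect_error(buildReference(sets, st$annotation), "different targets")
})

test_that("noise-free reference recovers planted profiles and classes", {
    p <- generateCellTypeProfiles(80, enrichedFraction = 0.3,
                                  enrichmentFactor = 5, seed = 34)
    iso <- lapply(setNames(nm = cellTypes()), function(ct)
        generateIsolatedCellTypeSamples(
            p$profiles, ct, 0, nReplicates = 2,
            noise = list(cv = 0, background = 50), crossHyb = 0.2,
            seed = 35))
    norm <- lapply(iso, function(d) mas5Normalize(d$data))
    ann <- unique(iso[[1]]$layout[, c("probeset_id", "gene_id")])
    ref <- buildReference(norm, ann)
    got <- refClass(ref)[names(p$plantedClass)]
    expect_equal(unname(got), unname(p$plantedClass))
})

test_that("marker validation reports matches and non-informative markers", {
    sig <- rbind(Mnx1 = c(100, 5, 5, 5, 5),
                 Gfap = c(2, 2, 400, 3, 1),
                 Itgam = c(1, 1, 1, 250, 2),
                 Dead = c(0, 0, 0, 0, 0))
    colnames(sig) <- cellTypes()
    ref <- CellTypeReference(sig)
    panel <- list(motor_neuron = "Mnx1", astrocyte = "Gfap",
                  microglia = c("Itgam", "Dead"))
    rep <- validateMarkers(ref, panel)
    expect_equal(rep$fraction_correct, 1)
    expect_equal(rep$table$status[rep$table$gene_id == "Dead"],
                 "non-informative")
    expect_error(validateMarkers(ref, list(microglia = character())),
                 "non-empty")
    expect_error(validateMarkers(ref, list(microglia = "Nope")), "absent")
})

test_that("DEG list annotation partitions every input gene", {
    sig <- matrix(runif(50, 50, 100), 10, 5,
                  dimnames = list(paste0("g", 1:10), cellTypes()))
    sig[1:3, "microglia"] <- 5000
    ref <- CellTypeReference(sig)
    out <- annotateDegList(c(paste0("g", 1:5), "absent1"), ref)
    expect_equal(sum(out$counts), 6)
    expect_true(out$table$missing[out$table$gene_id == "absent1"])
    expect_equal(out$table$class[out$table$gene_id == "absent1"],
                 "Unclassified")
    expect_equal(unname(out$counts["microglia"]), 3L,
                 ignore_attr = TRUE)
    set.seed(36)
    for (i in 1:10) {
        gl <- sample(c(paste0("g", 1:10), "x1", "x2"), sample(3:12, 1))
        expect_equal(sum(annotateDegList(gl, ref)$counts), length(gl))
    }
})

test_that("a 55 percent microglial planted DEG list classifies majority-microglia", {
    p <- generateCellTypeProfiles(2000, enrichedFraction = 0.5,
                                  enrichmentFactor = 5, seed = 37)
    layout <- makeChipLayout(rownames(p$profiles), seed = 37)
    iso <- lapply(setNames(nm = cellTypes()), function(ct)
        generateIsolatedCellTypeSamples(
            p$profiles, ct, 0, nReplicates = 3,
            noise = list(cv = 0.1, background = 50), crossHyb = 0.2,
            layout = layout, seed = 38 + match(ct, cellTypes())))
    norm <- lapply(iso, function(d) mas5Normalize(d$data))
    ann <- unique(layout[, c("probeset_id", "gene_id")])
    ref <- buildReference(norm, ann)
    mg <- names(p$plantedClass)[p$plantedClass == "microglia"]
    other <- setdiff(names(p$plantedClass), mg)
    set.seed(39)
    degList <- c(sample(mg, 110), sample(other, 90))
    counts <- annotateDegList(degList, ref)$counts
    expect_gt(counts[["microglia"]], length(degList) / 2)
})
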