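# Synthetic data generator: planted enrichment, mixture arithmetic,
# noise-free limits, determinism, composition constraints.

test_that("profile generator plants the requested enrichment structure", {
    p <- generateCellTypeProfiles(100, enrichedFraction = 0.2,
                                  enrichmentFactor = 5, seed = 1)
    expect_equal(sum(p$plantedClass != "Unclassified"), 20)
    expect_equal(sum(p$plantedClass == "Unclassified"), 80)
    # planted genes: labeled type is exactly factor x max(others)
    for (g in names(p$plantedClass)[p$plantedClass != "Unclassified"]) {
        ct <- p$plantedClass[g]
        row <- p$profiles[g, ]
        expect_equal(unname(row[ct]), 5 * max(row[names(row) != ct]),
                     tolerance = 1e-12)
    }
    # unenriched genes never reach a ratio of 4
    un <- p$profiles[p$plantedClass == "Unclassified", ]
    expect_true(all(apply(un, 1, max) / apply(un, 1, min) < 4))

    p0 <- generateCellTypeProfiles(50, enrichedFraction = 0, seed = 2)
    expect_true(all(p0$plantedClass == "Unclassified"))
    expect_error(generateCellTypeProfiles(5, seed = 1), "nGenes")
    expect_error(generateCellTypeProfiles(100, enrichmentFactor = 0.5),
                 "enrichmentFactor")
})

test_that("composition vectors validate weights and sum", {
    expect_error(compositionVector(
        c(motor_neuron = 0.5, neuron = 0.5, astrocyte = 0.1,
          microglia = 0, oligodendrocyte = 0)), "sum to 1")
    expect_error(compositionVector(
        c(motor_neuron = -0.1, neuron = 0.5, astrocyte = 0.3,
          microglia = 0.2, oligodendrocyte = 0.1)), ">= 0")
    cc <- defaultCompositions()
    expect_equal(sum(cc$control), 1)
    expect_equal(sum(cc$disease), 1)
    expect_lt(cc$disease["motor_neuron"], cc$control["motor_neuron"])
    expect_gt(cc$disease["microglia"], cc$control["microglia"])
    expect_gt(cc$disease["astrocyte"], cc$control["astrocyte"])
})

test_that("noise-free tissue samples equal the closed-form mixture", {
    p <- generateCellTypeProfiles(60, enrichedFraction = 0.3, seed = 3)
    comp <- defaultCompositions()$control
    out <- generateTissueSamples(p$profiles, comp, nReplicates = 2,
                                 noise = list(cv = 0, background = 0),
                                 crossHyb = 0, seed = 4)
    expect_true(all(mmIntensity(out$data) == 0))
    expected <- mixtureAbundance(p$profiles, comp)
    observed <- pmIntensity(out$data) / out$layout$affinity
    for (j in 1:2)
        expect_equal(unname(observed[, j]),
                     unname(expected[out$layout$gene_id]),
                     tolerance = 1e-9)
})

test_that("identical compositions and no effects give fold change 1", {
    p <- generateCellTypeProfiles(40, seed = 5)
    comp <- defaultCompositions()$control
    dis <- compositionVector(unclass(comp), "disease")
    a <- mixtureAbundance(p$profiles, comp)
    b <- mixtureAbundance(p$profiles, dis, NULL)
    expect_equal(a, b, tolerance = 1e-12)
})

test_that("composition shift amplifies a planted glial effect", {
    # a strongly microglia-dominant gene: expression in other cell types
    # is negligible, so the tissue signal tracks weight x cell-level FC
    prof <- matrix(10, 1, 5, dimnames = list("gMg", cellTypes()))
    prof[, "microglia"] <- 1000
    eff <- diseaseEffects("gMg", "microglia", 3)
    cc <- defaultCompositions()
    fcTissue <- mixtureAbundance(prof, cc$disease, eff)[1] /
        mixtureAbundance(prof, cc$control)[1]
    # gliosis raises the microglial weight (0.15 -> 0.23), so the
    # tissue-level fold change exceeds the planted threefold induction
    expect_gt(fcTissue, 3)
    hand <- (0.23 * 3000 + (0.04 + 0.26 + 0.32 + 0.15) * 10) /
        (0.15 * 1000 + (0.10 + 0.30 + 0.25 + 0.20) * 10)
    expect_equal(unname(fcTissue), hand, tolerance = 1e-12)
})

test_that("generators are bit-identical under a fixed seed", {
    p <- generateCellTypeProfiles(30, seed = 7)
    comp <- defaultCompositions()$control
    a <- generateTissueSamples(p$profiles, comp, seed = 8)
    b <- generateTissueSamples(p$profiles, comp, seed = 8)
    expect_identical(pmIntensity(a$data), pmIntensity(b$data))
    expect_identical(a$layout, b$layout)
    s1 <- simulateTissueStudy(nGenes = 50, nDeg = 5, seed = 9)
    s2 <- simulateTissueStudy(nGenes = 50, nDeg = 5, seed = 9)
    expect_identical(pmIntensity(s1$comparisons[[2]]$data),
                     pmIntensity(s2$comparisons[[2]]$data))
    expect_identical(plantedDeg(s1$truth), plantedDeg(s2$truth))
})

test_that("isolated samples follow the contamination mixture arithmetic", {
    p <- generateCellTypeProfiles(40, enrichedFraction = 0.5, seed = 10)
    pure <- generateIsolatedCellTypeSamples(
        p$profiles, "astrocyte", 0, nReplicates = 2,
        noise = list(cv = 0, background = 0), crossHyb = 0, seed = 11)
    expect_equal(unname(pmIntensity(pure$data)[, 1] / pure$layout$affinity),
                 unname(p$profiles[pure$layout$gene_id, "astrocyte"]),
                 tolerance = 1e-9)
    cont <- generateIsolatedCellTypeSamples(
        p$profiles, "astrocyte", 0.1, nReplicates = 2,
        noise = list(cv = 0, background = 0), crossHyb = 0, seed = 11)
    w <- setNames(rep(0.025, 5), cellTypes()); w["astrocyte"] <- 0.9
    expected <- drop(p$profiles %*% w)
    expect_equal(unname(pmIntensity(cont$data)[, 1] / cont$layout$affinity),
                 unname(expected[cont$layout$gene_id]), tolerance = 1e-9)
    # a microglia-class marker appears at ~ (f/4) x its microglial level
    mg <- names(p$plantedClass)[p$plantedClass == "microglia"][1]
    expect_equal(expected[mg],
                 0.9 * p$profiles[mg, "astrocyte"] +
                     0.025 * sum(p$profiles[mg, cellTypes() != "astrocyte"]),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_error(generateIsolatedCellTypeSamples(p$profiles, "astrocyte", 0.5),
                 "contaminationFraction")
})

test_that("planted ectopic induction dwarfs pure contamination leakage", {
    p <- generateCellTypeProfiles(60, enrichedFraction = 0.5, seed = 12)
    mg <- names(p$plantedClass)[p$plantedClass == "microglia"]
    ecto <- mg[1]; markers <- mg[2:4]
    eff <- rbind(
        diseaseEffects(markers, "microglia", c(8.5, 3.1, 0.6)),
        diseaseEffects(ecto, "astrocyte", 50, ectopic = TRUE))
    w <- setNames(rep(0.025, 5), cellTypes()); w["astrocyte"] <- 0.9
    fc <- mixtureAbundance(p$profiles, w, eff) /
        mixtureAbundance(p$profiles, w)
    # contamination leakage can never exceed the strongest planted
    # microglial induction, while the ectopic gene blows far past it
    expect_lt(max(fc[markers]), 8.5)
    expect_gt(fc[ecto], 3 * max(fc[markers]))
    expect_gt(fc[ecto], 10)
})

test_that("disease composition shift moves markers the expected way", {
    p <- generateCellTypeProfiles(200, enrichedFraction = 0.3, seed = 13)
    cls <- p$plantedClass
    cc <- defaultCompositions()
    for (s in 1:5) {
        ctl <- generateTissueSamples(p$profiles, cc$control,
                                     noise = list(cv = 0.15, background = 50),
                                     seed = 100 + s, label = "ctl")
        dis <- generateTissueSamples(p$profiles, cc$disease,
                                     noise = list(cv = 0.15, background = 50),
                                     layout = ctl$layout, seed = 200 + s,
                                     label = "dis")
        mCtl <- mas5Normalize(ctl$data)
        mDis <- mas5Normalize(dis$data)
        ann <- unique(ctl$layout[, c("probeset_id", "gene_id")])
        fc <- cellTypeFoldChanges(mDis, mCtl, ann)
        mnFc <- fc[names(cls)[cls == "motor_neuron"]]
        glFc <- fc[names(cls)[cls %in% c("microglia", "astrocyte")]]
        expect_lt(median(mnFc), 1)
        expect_gt(median(glFc), 1)
    }
})

test_that("planted truth serializes losslessly", {
    tr <- SyntheticTruth(
        plantedDeg = c("g1", "g3"),
        plantedClass = c(g1 = "microglia", g2 = "Unclassified",
                         g3 = "astrocyte"),
        plantedEctopic = data.frame(gene_id = "g1", cell_type = "astrocyte"),
        compositions = lapply(defaultCompositions(), unclass),
        noise = list(cv = 0.15, background = 50), seed = 42L)
    f <- tempfile(fileext = ".json")
    writeTruth(tr, f)
    back <- readTruth(f)
    expect_identical(plantedDeg(back), plantedDeg(tr))
    expect_identical(plantedClass(back), plantedClass(tr))
    expect_identical(plantedEctopic(back)$gene_id,
                     plantedEctopic(tr)$gene_id)
    expect_equal(back@compositions, tr@compositions)
    expect_identical(back@seed, tr@seed)
    # an ectopic entry in the gene's own home type is invalid
    expect_error(SyntheticTruth(
        plantedClass = c(g1 = "microglia"),
        plantedEctopic = data.frame(gene_id = "g1",
                                    cell_type = "microglia")),
        "ectopic")
})
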