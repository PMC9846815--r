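# MAS5-style engine: biweight, ideal mismatch, signal, detection,
# scaling, and the compiled whole-dataset path.

test_that("tukey biweight handles constants, singletons and outliers", {
    expect_equal(tukeyBiweight(rep(7, 5)), 7)
    expect_equal(tukeyBiweight(3.14), 3.14)
    # hand-computed: median 3, MAD 1, outlier 100 gets weight 0
    expect_equal(tukeyBiweight(c(1, 2, 3, 4, 100), c = 5, epsilon = 1e-4),
                 2.6023, tolerance = 1e-4)
    expect_error(tukeyBiweight(numeric(0)), "empty")
    set.seed(1)
    for (i in 1:20) {
        x <- rlnorm(sample(3:15, 1), 5, 1)
        expect_equal(tukeyBiweight(x), bruteBiweight(x), tolerance = 1e-12)
    }
})

test_that("ideal mismatch follows the three branch rules and stays below PM", {
    p <- mas5Params()
    expect_equal(idealMismatch(1000, 200), 200)
    # all mm >= pm forces the SB-based branches
    pm <- c(100, 120, 90, 110)
    mm <- c(150, 160, 140, 150)
    SB <- tukeyBiweight(log2(pm / mm))
    im <- idealMismatch(pm, mm)
    expect_true(SB <= p$contrastTau)  # negative SB here
    expect_equal(im, pm / 2^(p$contrastTau /
                                 (1 + (p$contrastTau - SB) / p$scaleTau)),
                 tolerance = 1e-12)
    # mixed pairs where SB > contrastTau: uncontested pairs use im = pm/2^SB
    pm2 <- c(1000, 800, 1200, 100)
    mm2 <- c(100, 90, 140, 160)
    SB2 <- tukeyBiweight(log2(pm2 / mm2))
    expect_gt(SB2, p$contrastTau)
    im2 <- idealMismatch(pm2, mm2)
    expect_equal(im2[4], pm2[4] / 2^SB2, tolerance = 1e-12)
    expect_true(all(im2 < pm2))
    set.seed(2)
    for (i in 1:20) {
        pr <- randomPairs(11)
        expect_true(all(idealMismatch(pr$pm, pr$mm) < pr$pm))
    }
})

test_that("probeset signal matches its closed forms and a brute-force oracle", {
    expect_equal(probesetSignal(1000, 200), 800)
    # identical pm - im = 64 across pairs
    expect_equal(probesetSignal(rep(100, 5), rep(36, 5)), 64)
    set.seed(3)
    for (i in 1:50) {
        pr <- randomPairs(sample(4:20, 1))
        expect_equal(probesetSignal(pr$pm, pr$mm),
                     bruteSignal(pr$pm, pr$mm), tolerance = 1e-9)
    }
})

test_that("detection p-value is exact for small probesets", {
    # all discrimination scores far above tau: all mass at the maximum
    expect_equal(detectionPvalue(rep(1000, 4), rep(10, 4)), 1 / 16)
    expect_equal(detectionPvalue(rep(1000, 5), rep(10, 5)), 1 / 32)
    # degenerate: every score equals tau exactly -> all zeros dropped
    tau <- (1.015 - 0.985) / (1.015 + 0.985)
    expect_equal(detectionPvalue(rep(1.015, 4), rep(0.985, 4),
                                 mas5Params(tau = tau)), 1)
    expect_error(detectionPvalue(c(1, -1), c(-1, 1)))
})

test_that("detection p-value equals literal sign-assignment enumeration", {
    set.seed(4)
    for (i in 1:120) {
        n <- sample(1:12, 1)
        pr <- randomPairs(n, allowTies = i %% 3 == 0)
        expect_equal(detectionPvalue(pr$pm, pr$mm),
                     enumDetectionP(pr$pm, pr$mm), tolerance = 1e-12)
    }
})

test_that("detection is monotone in PM", {
    set.seed(5)
    pr <- randomPairs(11)
    p0 <- detectionPvalue(pr$pm, pr$mm)
    for (k in c(1.2, 2, 5)) {
        pk <- detectionPvalue(pr$pm * k, pr$mm)
        expect_lte(pk, p0 + 1e-12)
        p0 <- pk
    }
})

test_that("normal approximation agrees with exact enumeration at the crossover", {
    set.seed(6)
    for (i in 1:30) {
        pr <- randomPairs(12)
        pExact <- detectionPvalue(pr$pm, pr$mm, mas5Params(exactLimit = 12))
        pNorm <- detectionPvalue(pr$pm, pr$mm, mas5Params(exactLimit = 11))
        expect_lt(abs(pExact - pNorm), 0.01)
    }
})

test_that("detection calls threshold correctly", {
    expect_equal(detectionCall(0.03125, alpha1 = 0.04), "P")
    expect_equal(detectionCall(0.0625, alpha2 = 0.06), "A")
    expect_equal(detectionCall(0.05), "M")
    expect_equal(detectionCall(c(0.01, 0.05, 0.9)), c("P", "M", "A"))
})

test_that("per-array scaling hits the target and preserves order", {
    sc <- scaleArray(c(100, 200, 300, 400, 500), target = 500, trim = 0)
    expect_equal(sc$scale_factor, 5 / 3)
    expect_equal(mean(sc$scaled), 500)
    at <- scaleArray(c(400, 500, 600), target = 500, trim = 0)
    expect_equal(at$scale_factor, 1)
    set.seed(7)
    for (i in 1:20) {
        x <- rlnorm(sample(20:2000, 1), 5, 1.5)
        sc <- scaleArray(x, target = 500, trim = 0.02)
        expect_equal(trimmedMean(sc$scaled, 0.02), 500, tolerance = 1e-6)
        expect_equal(order(sc$scaled), order(x))
    }
})

test_that("compiled dataset path equals the scalar reference implementations", {
    set.seed(8)
    nset <- 30
    ps <- rep(sprintf("ps%02d", seq_len(nset)), each = 11)
    pm <- matrix(runif(length(ps) * 3, 50, 3000), ncol = 3,
                 dimnames = list(NULL, c("a", "b", "c")))
    mm <- matrix(runif(length(ps) * 3, 10, 2000), ncol = 3)
    x <- ProbePairSet(pm, mm, ps)
    res <- mas5Normalize(x)
    sf <- scaleFactors(res)
    for (j in 1:3) {
        for (s in unique(ps)) {
            rows <- which(ps == s)
            expect_equal(unname(exprSignal(res)[s, j] / sf[j]),
                         probesetSignal(pm[rows, j], mm[rows, j]),
                         tolerance = 1e-9)
            expect_equal(detectionP(res)[s, j],
                         detectionPvalue(pm[rows, j], mm[rows, j]),
                         tolerance = 1e-12)
        }
    }
})

test_that("signals are invariant to probe-pair order within probesets", {
    set.seed(9)
    ps <- rep(c("psA", "psB", "psC"), each = 8)
    pm <- matrix(runif(48, 100, 2000), ncol = 2,
                 dimnames = list(NULL, c("s1", "s2")))
    mm <- matrix(runif(48, 20, 1500), ncol = 2)
    x1 <- mas5Normalize(ProbePairSet(pm, mm, ps))
    perm <- c(sample(1:8), sample(9:16), sample(17:24))
    x2 <- mas5Normalize(ProbePairSet(pm[perm, ], mm[perm, ], ps[perm]))
    expect_equal(exprSignal(x1), exprSignal(x2), tolerance = 1e-12)
    expect_equal(detectionP(x1), detectionP(x2), tolerance = 1e-12)
})

test_that("scaling is per-array: adding samples never changes existing ones", {
    set.seed(10)
    ps <- rep(sprintf("p%03d", 1:100), each = 11)
    pm <- matrix(runif(1100 * 6, 50, 4000), ncol = 6,
                 dimnames = list(NULL, paste0("s", 1:6)))
    mm <- matrix(runif(1100 * 6, 10, 2500), ncol = 6)
    sub <- mas5Normalize(ProbePairSet(pm[, 1:3], mm[, 1:3], ps))
    full <- mas5Normalize(ProbePairSet(pm, mm, ps))
    expect_identical(exprSignal(full)[, 1:3], exprSignal(sub))
    expect_identical(detectionCalls(full)[, 1:3], detectionCalls(sub))
})

test_that("multiplying one array by k leaves its scaled signals unchanged", {
    set.seed(11)
    ps <- rep(sprintf("p%03d", 1:80), each = 11)
    pm <- matrix(runif(880 * 2, 200, 4000), ncol = 2,
                 dimnames = list(NULL, c("s1", "s2")))
    mm <- pm * runif(880 * 2, 0.05, 0.6)
    base <- mas5Normalize(ProbePairSet(pm, mm, ps))
    k <- 3.7
    pm2 <- pm; mm2 <- mm
    pm2[, 2] <- pm[, 2] * k; mm2[, 2] <- mm[, 2] * k
    scaled <- mas5Normalize(ProbePairSet(pm2, mm2, ps))
    # unscaled signals pick up the factor k ...
    expect_equal(exprSignal(scaled)[, 2] / scaleFactors(scaled)[2],
                 k * exprSignal(base)[, 2] / scaleFactors(base)[2],
                 tolerance = 1e-9)
    # ... and the global scaling removes it
    expect_equal(exprSignal(scaled)[, 2], exprSignal(base)[, 2],
                 tolerance = 1e-6)
    expect_equal(exprSignal(scaled)[, 1], exprSignal(base)[, 1])
})

test_that("probe-pair containers validate their contents", {
    pm <- matrix(c(1, 2, 3, 4), 2)
    expect_error(ProbePairSet(pm, -pm, c("a", "a")), "mm")
    expect_error(ProbePairSet(pm * 0, pm, c("a", "a")), "pm")
    expect_error(ProbePairSet(pm, pm * 0.1, c("a", "a"), c(1, 1)),
                 "duplicated")
})
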