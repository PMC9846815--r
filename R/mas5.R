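# MAS5-style probe-level normalization engine.
#
# The scalar functions below are straightforward reference implementations
# of each step; mas5Normalize() runs the same arithmetic through a compiled
# path for whole datasets. Equivalence of the two routes is asserted in the
# test suite.

#' MAS5 engine parameters
#'
#' Default constants of the MAS5-style engine, following the published
#' Affymetrix statistical algorithms description. All are overridable.
#'
#' @param tau Discrimination-score offset for the detection test (0.015).
#' @param alpha1,alpha2 Detection-call thresholds: p < alpha1 is Present,
#'   alpha1 <= p < alpha2 Marginal, otherwise Absent (0.04, 0.06).
#' @param c,epsilon Tukey biweight tuning constant and stabilizer (5, 1e-4).
#' @param contrastTau,scaleTau Ideal-mismatch branch constants (0.03, 10).
#' @param deltaFloor Floor for PM - IM before taking logs (2^-20).
#' @param scaleTarget Trimmed-mean target of per-array global scaling (500).
#' @param trim Fraction trimmed from each tail of the signal distribution
#'   when computing the scaling trimmed mean (0.02).
#' @param exactLimit Largest number of probe pairs for which the detection
#'   p-value is computed by exact enumeration (12); the normal approximation
#'   with continuity and tie correction is used above.
#'
#' @return Named list of parameters.
#' @export
#' @examples
#' mas5Params(scaleTarget = 100)
mas5Params <- function(tau = 0.015, alpha1 = 0.04, alpha2 = 0.06,
                       c = 5, epsilon = 1e-4,
                       contrastTau = 0.03, scaleTau = 10,
                       deltaFloor = 2^-20,
                       scaleTarget = 500, trim = 0.02,
                       exactLimit = 12L) {
    stopifnot(tau >= 0, alpha1 > 0, alpha2 > alpha1, alpha2 < 1,
              c > 0, epsilon > 0, contrastTau > 0, scaleTau > 0,
              deltaFloor > 0, scaleTarget > 0, trim >= 0, trim < 0.5)
    list(tau = tau, alpha1 = alpha1, alpha2 = alpha2, c = c,
         epsilon = epsilon, contrastTau = contrastTau, scaleTau = scaleTau,
         deltaFloor = deltaFloor, scaleTarget = scaleTarget, trim = trim,
         exactLimit = as.integer(exactLimit))
}

#' One-step Tukey biweight robust mean
#'
#' Weighted mean with biweight weights computed in a single pass from the
#' median and the median absolute deviation:
#' \eqn{u_i = (x_i - med) / (c \cdot MAD + \epsilon)},
#' \eqn{w_i = (1 - u_i^2)^2} for \eqn{|u_i| < 1} and 0 otherwise.
#'
#' @param x Non-empty numeric vector.
#' @param c Tuning constant (default 5).
#' @param epsilon Stabilizer added to \code{c * MAD} (default 1e-4).
#' @return The robust mean.
#' @export
#' @examples
#' tukeyBiweight(c(1, 2, 3, 4, 100))  # outlier receives zero weight
tukeyBiweight <- function(x, c = 5, epsilon = 1e-4) {
    if (length(x) == 0L) stop("empty vector")
    if (!all(is.finite(x))) stop("non-finite values")
    m <- median(x)
    s <- median(abs(x - m))
    u <- (x - m) / (c * s + epsilon)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    sum(w * x) / sum(w)
}

#' Ideal mismatch
#'
#' The mismatch value actually subtracted from PM: the observed MM when it
#' is informative (MM < PM), otherwise an estimate derived from the
#' probeset-wide specific background SB, the biweight of
#' \code{log2(pm/mm)} over the probeset's pairs.
#'
#' @param pm,mm Probe-pair intensity vectors for one probeset.
#' @param params See \code{\link{mas5Params}}.
#' @return Numeric vector of ideal-mismatch values, each strictly below its
#'   PM.
#' @export
idealMismatch <- function(pm, mm, params = mas5Params()) {
    .checkPairs(pm, mm)
    SB <- .specificBackground(pm, mm, params)
    ifelse(mm < pm, mm,
           ifelse(rep(SB > params$contrastTau, length(pm)),
                  pm / 2^SB,
                  pm / 2^(params$contrastTau /
                              (1 + (params$contrastTau - SB) / params$scaleTau))))
}

.specificBackground <- function(pm, mm, params) {
    ok <- pm > 0 & mm > 0
    if (!any(ok)) return(0)
    tukeyBiweight(log2(pm[ok] / mm[ok]), c = params$c,
                  epsilon = params$epsilon)
}

.checkPairs <- function(pm, mm) {
    stopifnot(length(pm) == length(mm), length(pm) >= 1L,
              all(is.finite(pm)), all(is.finite(mm)),
              all(pm > 0), all(mm >= 0))
}

#' Probeset signal
#'
#' Antilog of the biweight mean of \code{log2(max(pm - im, deltaFloor))}
#' over a probeset's probe pairs (unscaled MAS5-style signal).
#'
#' @inheritParams idealMismatch
#' @return A positive finite scalar signal.
#' @export
#' @examples
#' probesetSignal(pm = 1000, mm = 200)  # single pair: 800
probesetSignal <- function(pm, mm, params = mas5Params()) {
    .checkPairs(pm, mm)
    im <- idealMismatch(pm, mm, params)
    v <- log2(pmax(pm - im, params$deltaFloor))
    2^tukeyBiweight(v, c = params$c, epsilon = params$epsilon)
}

#' Detection p-value
#'
#' One-sided Wilcoxon signed-rank test that the discrimination scores
#' \eqn{R_i = (PM_i - MM_i)/(PM_i + MM_i)} exceed \code{tau}. Pairs with
#' \eqn{R_i = \tau} exactly are dropped before ranking (signed-rank zero
#' convention). For up to \code{exactLimit} informative pairs the p-value
#' enumerates all \eqn{2^n} sign assignments exactly; above that a normal
#' approximation with continuity and tie correction is used.
#'
#' @inheritParams idealMismatch
#' @return p-value in (0, 1].
#' @export
#' @examples
#' detectionPvalue(pm = rep(1000, 4), mm = rep(10, 4))  # 1/16
detectionPvalue <- function(pm, mm, params = mas5Params()) {
    .checkPairs(pm, mm)
    if (any(pm + mm <= 0)) stop("pm + mm must be positive for every pair")
    R <- (pm - mm) / (pm + mm)
    d <- R - params$tau
    d <- d[d != 0]
    n <- length(d)
    if (n == 0L) return(1)
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    if (n <= params$exactLimit) {
        signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
        Wall <- as.vector(signs %*% r)
        return(mean(Wall >= W - 1e-9))
    }
    mu <- n * (n + 1) / 4
    ties <- table(r)
    v <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    if (v <= 0) return(1)
    min(1, max(pnorm((W - mu - 0.5) / sqrt(v), lower.tail = FALSE), 1e-300))
}

#' Present/Marginal/Absent call
#'
#' @param p Detection p-value(s).
#' @param alpha1,alpha2 Call thresholds (defaults 0.04 and 0.06).
#' @return Character vector of calls: \code{"P"} if \code{p < alpha1},
#'   \code{"M"} if \code{alpha1 <= p < alpha2}, else \code{"A"}.
#' @export
#' @examples
#' detectionCall(c(0.01, 0.05, 0.2))
detectionCall <- function(p, alpha1 = 0.04, alpha2 = 0.06) {
    stopifnot(alpha1 < alpha2)
    ifelse(p < alpha1, "P", ifelse(p < alpha2, "M", "A"))
}

#' Trimmed mean with deterministic tail counts
#'
#' Removes \code{floor(trim * n)} values from each tail before averaging,
#' so the trim is deterministic for small n.
#'
#' @param x Numeric vector.
#' @param trim Fraction per tail.
#' @return Scalar mean of the retained values.
#' @export
trimmedMean <- function(x, trim = 0.02) {
    n <- length(x)
    k <- floor(trim * n)
    if (2 * k >= n) stop("trim removes all values")
    s <- sort(x)
    mean(s[(k + 1):(n - k)])
}

#' Per-array global scaling
#'
#' Multiplies one array's signals by \code{target / trimmedMean(signals)}
#' so every array's trimmed mean sits at the common target. Scaling is
#' strictly per-array: a sample's scaled signals never depend on which
#' other samples are in the dataset.
#'
#' @param signals Numeric vector of unscaled probeset signals for one array.
#' @param target Trimmed-mean target (default 500).
#' @param trim Fraction trimmed per tail (default 0.02).
#' @return List with \code{scaled} signals and the \code{scale_factor}.
#' @export
#' @examples
#' scaleArray(c(100, 200, 300, 400, 500), target = 500, trim = 0)
scaleArray <- function(signals, target = 500, trim = 0.02) {
    tm <- trimmedMean(signals, trim)
    if (tm <= 0) stop("non-positive trimmed mean")
    sf <- target / tm
    list(scaled = signals * sf, scale_factor = sf)
}

#' MAS5-style normalization of a probe-level dataset
#'
#' Computes, per probeset and sample, the biweight probeset signal over
#' ideal-mismatch-corrected probe pairs together with the signed-rank
#' detection p-value and P/M/A call, then applies per-array trimmed-mean
#' scaling to the signals. The per-probeset arithmetic runs through a
#' compiled path identical to \code{\link{probesetSignal}} and
#' \code{\link{detectionPvalue}}.
#'
#' @param x A \code{\link{ProbePairSet}}.
#' @param params See \code{\link{mas5Params}}.
#' @return A \code{\link{MAS5Set}}.
#' @export
mas5Normalize <- function(x, params = mas5Params()) {
    stopifnot(is(x, "ProbePairSet"))
    ps <- probesetIds(x)
    lev <- unique(ps)
    grp <- match(ps, lev) - 1L
    res <- .mas5_core(pmIntensity(x), mmIntensity(x), grp, length(lev),
                      params$tau, params$c, params$epsilon,
                      params$contrastTau, params$scaleTau, params$deltaFloor,
                      params$exactLimit)
    sig <- res$signal
    detp <- res$detp
    dimnames(sig) <- dimnames(detp) <- list(lev, colnames(x))
    sf <- numeric(ncol(sig))
    for (j in seq_len(ncol(sig))) {
        sc <- scaleArray(sig[, j], target = params$scaleTarget,
                         trim = params$trim)
        sig[, j] <- sc$scaled
        sf[j] <- sc$scale_factor
    }
    names(sf) <- colnames(x)
    calls <- matrix(detectionCall(detp, params$alpha1, params$alpha2),
                    nrow = nrow(detp), dimnames = dimnames(detp))
    MAS5Set(signal = sig, detectionP = detp, call = calls,
            scaleFactors = sf, params = params)
}
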