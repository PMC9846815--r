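# Independent oracles used across the suite. These deliberately re-derive
# each quantity from first principles (literal enumeration, closed-form
# mixture arithmetic) rather than reusing package internals.

# Literal enumeration of all 2^n sign assignments of the signed-rank
# statistic for the detection test.
enumDetectionP <- function(pm, mm, tau = 0.015) {
    R <- (pm - mm) / (pm + mm)
    d <- R - tau
    d <- d[d != 0]
    n <- length(d)
    if (n == 0) return(1)
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    cnt <- 0L
    for (mask in 0:(2^n - 1)) {
        s <- as.integer(intToBits(mask))[seq_len(n)]
        if (sum(r[s == 1L]) >= W - 1e-9) cnt <- cnt + 1L
    }
    cnt / 2^n
}

# Step-by-step biweight: explicit weights, no shortcuts.
bruteBiweight <- function(x, c = 5, eps = 1e-4) {
    m <- median(x)
    S <- median(abs(x - m))
    u <- (x - m) / (c * S + eps)
    w <- numeric(length(x))
    for (i in seq_along(x))
        if (abs(u[i]) < 1) w[i] <- (1 - u[i]^2)^2
    sum(w * x) / sum(w)
}

# Full MAS5 probeset signal recomputed from the published step formulas.
bruteSignal <- function(pm, mm, p = mascot::mas5Params()) {
    ok <- pm > 0 & mm > 0
    SB <- if (any(ok)) bruteBiweight(log2(pm[ok] / mm[ok]), p$c, p$epsilon) else 0
    im <- numeric(length(pm))
    for (i in seq_along(pm)) {
        if (mm[i] < pm[i]) im[i] <- mm[i]
        else if (SB > p$contrastTau) im[i] <- pm[i] / 2^SB
        else im[i] <- pm[i] /
                2^(p$contrastTau / (1 + (p$contrastTau - SB) / p$scaleTau))
    }
    2^bruteBiweight(log2(pmax(pm - im, p$deltaFloor)), p$c, p$epsilon)
}

# Upper-tail hypergeometric P(X >= k) by exhaustive enumeration of every
# n-subset of an N-gene universe whose first m genes form the category.
enumHyperTail <- function(N, m, n, k) {
    if (k <= 0) return(1)
    hits <- 0L
    total <- 0L
    for (s in utils::combn(N, n, simplify = FALSE)) {
        total <- total + 1L
        if (sum(s <= m) >= k) hits <- hits + 1L
    }
    hits / total
}

# Combinatorial-sum tail (independent of phyper's implementation).
sumHyperTail <- function(N, m, n, k) {
    i <- max(k, max(0, n - (N - m))):min(m, n)
    if (k > min(m, n)) return(0)
    sum(choose(m, i) * choose(N - m, n - i)) / choose(N, n)
}

randomPairs <- function(n, allowTies = FALSE) {
    pm <- runif(n, 50, 2000)
    mm <- runif(n, 10, 1500)
    if (allowTies && n >= 4) {
        mm[2] <- mm[1] * pm[2] / pm[1]  # duplicate discrimination score
    }
    list(pm = pm, mm = mm)
}

smallExprSet <- function(signal, calls = NULL, samples = colnames(signal)) {
    if (is.null(calls))
        calls <- matrix("P", nrow(signal), ncol(signal))
    dimnames(calls) <- dimnames(signal)
    MAS5Set(signal = signal,
            detectionP = matrix(0.01, nrow(signal), ncol(signal),
                                dimnames = dimnames(signal)),
            call = calls,
            scaleFactors = setNames(rep(1, ncol(signal)), samples))
}
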