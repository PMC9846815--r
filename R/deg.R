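# Multi-comparison differential expression pipeline: detection-call
# filtering, fold-change thresholding, Welch t statistics with BH
# correction, same-direction intersection across comparisons, and
# deduplication of probesets to genes.

#' Detection-call (FLAG) filter
#'
#' A probeset is retained when it is called Present or Marginal in at least
#' \code{minPM} of the samples of a comparison, pooling the mutant and
#' control groups (default: 3 of all 6).
#'
#' @param calls Character vector of P/M/A calls across the comparison's
#'   samples.
#' @param minPM Minimum number of P or M calls (default 3).
#' @return Logical.
#' @export
#' @examples
#' flagCallFilter(c("P", "P", "M", "A", "A", "A"))  # TRUE
#' flagCallFilter(c("P", "A", "A", "M", "A", "A"))  # FALSE
flagCallFilter <- function(calls, minPM = 3) {
    stopifnot(all(calls %in% c("P", "M", "A")))
    sum(calls %in% c("P", "M")) >= minPM
}

#' Fold change between group means
#'
#' Ratio of mutant to control mean signal, reported as-is (down-regulation
#' gives values below 1).
#'
#' @param mutant,control Numeric signal vectors.
#' @return The ratio of means.
#' @export
#' @examples
#' foldChange(c(350, 400, 450), c(90, 100, 110))  # 4
foldChange <- function(mutant, control) {
    cm <- mean(control)
    if (cm <= 0) stop("control mean must be > 0")
    mean(mutant) / cm
}

#' Welch's unpaired t-test p-value
#'
#' Two-sided p from the unequal-variance t statistic with
#' Welch-Satterthwaite degrees of freedom. Degenerate inputs follow a
#' documented convention: if both groups have zero variance, p is 1 when
#' the means agree and 0 when they differ.
#'
#' @param groupA,groupB Numeric vectors with at least 2 values each.
#' @return Two-sided p-value.
#' @export
#' @examples
#' welchTTest(c(1, 2, 3), c(2, 3, 4))
welchTTest <- function(groupA, groupB) {
    stopifnot(length(groupA) >= 2, length(groupB) >= 2)
    if (var(groupA) == 0 && var(groupB) == 0)
        return(if (mean(groupA) == mean(groupB)) 1 else 0)
    stats::t.test(groupA, groupB, var.equal = FALSE)$p.value
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR q-values via \code{\link[stats]{p.adjust}}.
#'
#' @param p Numeric vector of p-values.
#' @return q-values, monotone in p and clipped at 1.
#' @export
bhAdjust <- function(p) p.adjust(p, method = "BH")

# Vectorized Welch test over rows of two matrices (cross-checked against
# stats::t.test in the test suite).
.rowWelch <- function(a, b) {
    n1 <- ncol(a); n2 <- ncol(b)
    m1 <- rowMeans(a); m2 <- rowMeans(b)
    v1 <- rowSums((a - m1)^2) / (n1 - 1)
    v2 <- rowSums((b - m2)^2) / (n2 - 1)
    se2 <- v1 / n1 + v2 / n2
    tt <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * pt(-abs(tt), df)
    zero <- se2 == 0
    if (any(zero)) p[zero] <- ifelse(m1[zero] == m2[zero], 1, 0)
    p
}

#' Single-comparison differential expression
#'
#' For one mutant-vs-control comparison: applies the FLAG-call filter,
#' computes the fold change of group means, the Welch t p-value and the
#' BH q-value (adjusted across the filter-passing probesets), and marks
#' probesets exceeding the fold-change threshold in either direction.
#'
#' @param x A \code{\link{MAS5Set}} holding the comparison's samples.
#' @param mutant,control Sample (column) names of the two groups; must be
#'   disjoint and non-empty.
#' @param fcThreshold Fold-change threshold (default 2: more than twofold
#'   up or down).
#' @param fdr FDR level used when \code{requireFdr} is set (default 0.05).
#' @param requireFdr Also require q < fdr for DEG status (default FALSE;
#'   q-values are always reported).
#' @param minPM FLAG-call minimum (default 3).
#' @return data.frame with one row per probeset: fold_change, p_value,
#'   q_value (NA for filtered probesets), flag_pass, direction
#'   ("up"/"down") and deg (logical).
#' @export
comparisonDegs <- function(x, mutant, control, fcThreshold = 2,
                           fdr = 0.05, requireFdr = FALSE, minPM = 3) {
    stopifnot(is(x, "MAS5Set"), length(mutant) > 0, length(control) > 0,
              !anyDuplicated(c(mutant, control)), fcThreshold >= 1)
    miss <- setdiff(c(mutant, control), colnames(x))
    if (length(miss)) stop("unknown samples: ", paste(miss, collapse = ", "))
    sig <- exprSignal(x)
    calls <- detectionCalls(x)[, c(mutant, control), drop = FALSE]
    flag <- rowSums(calls == "P" | calls == "M") >= minPM
    a <- sig[, mutant, drop = FALSE]
    b <- sig[, control, drop = FALSE]
    fc <- rowMeans(a) / rowMeans(b)
    p <- .rowWelch(a, b)
    q <- rep(NA_real_, nrow(sig))
    q[flag] <- bhAdjust(p[flag])
    deg <- flag & (fc > fcThreshold | fc < 1 / fcThreshold)
    if (requireFdr) deg <- deg & !is.na(q) & q < fdr
    data.frame(probeset_id = rownames(sig), fold_change = fc,
               p_value = p, q_value = q, flag_pass = flag,
               direction = ifelse(fc > 1, "up", "down"),
               deg = deg, row.names = NULL)
}

#' Intersect DEG sets across comparisons
#'
#' Entities commonly changed in every comparison. When comparison result
#' tables are supplied, direction consistency is required by default: a
#' probeset counts only if it moves the same way (up or down) in all
#' comparisons.
#'
#' @param results List (length >= 2) of \code{\link{comparisonDegs}}
#'   tables, or of plain probeset id character vectors.
#' @param requireDirection Require a common direction (default TRUE;
#'   ignored for plain id vectors).
#' @return Character vector of common probeset ids.
#' @export
intersectComparisons <- function(results, requireDirection = TRUE) {
    stopifnot(is.list(results), length(results) >= 2)
    if (all(vapply(results, is.character, logical(1))))
        return(Reduce(intersect, results))
    sets <- lapply(results, function(r) r$probeset_id[r$deg])
    common <- Reduce(intersect, sets)
    if (requireDirection && length(common)) {
        dirs <- vapply(results, function(r)
            r$direction[match(common, r$probeset_id)],
            character(length(common)))
        dirs <- matrix(dirs, nrow = length(common))
        keep <- apply(dirs, 1L, function(d) length(unique(d)) == 1L)
        common <- common[keep]
    }
    common
}

#' Collapse probesets to unique genes
#'
#' Deduplicates an intersected probeset list to one record per gene. When
#' several probesets map to the same gene, the representative is the one
#' with the largest mean absolute log2 fold change over the comparisons.
#' Probesets missing from the annotation are routed to an
#' \code{"unannotated"} attribute and excluded from the gene list.
#'
#' @param probesets Character vector of probeset ids.
#' @param annotation data.frame with columns probeset_id, gene_id.
#' @param results Optional list of \code{\link{comparisonDegs}} tables used
#'   to score representatives; without it the first probeset per gene is
#'   kept.
#' @return data.frame with gene_id and representative probeset_id (and
#'   mean_abs_log2_fc when scored); attribute \code{"unannotated"} lists
#'   dropped probesets.
#' @export
collapseToGenes <- function(probesets, annotation, results = NULL) {
    stopifnot(all(c("probeset_id", "gene_id") %in% colnames(annotation)))
    idx <- match(probesets, annotation$probeset_id)
    unann <- probesets[is.na(idx)]
    if (length(unann))
        message(length(unann), " probeset(s) missing from annotation; excluded")
    keep <- !is.na(idx)
    df <- data.frame(probeset_id = probesets[keep],
                     gene_id = annotation$gene_id[idx[keep]])
    if (!is.null(results) && nrow(df)) {
        score <- rowMeans(vapply(results, function(r)
            abs(log2(r$fold_change[match(df$probeset_id, r$probeset_id)])),
            numeric(nrow(df))))
        df$mean_abs_log2_fc <- score
        df <- df[order(df$gene_id, -score), ]
    }
    df <- df[!duplicated(df$gene_id), , drop = FALSE]
    rownames(df) <- NULL
    attr(df, "unannotated") <- unann
    df
}

#' Run the full multi-comparison DEG extraction
#'
#' Normalizes nothing itself: takes one \code{\link{MAS5Set}} per
#' comparison, extracts per-comparison DEGs, intersects them with
#' direction consistency, and collapses the surviving entities to unique
#' genes.
#'
#' @param comparisons Named list; each element a list with elements
#'   \code{expr} (a \code{MAS5Set}), \code{mutant} and \code{control}
#'   (sample names).
#' @param annotation Probeset -> gene annotation data.frame.
#' @inheritParams comparisonDegs
#' @inheritParams intersectComparisons
#' @return List with \code{per_comparison} result tables, the intersected
#'   \code{entities}, and the deduplicated \code{genes} table.
#' @export
extractDegs <- function(comparisons, annotation, fcThreshold = 2,
                        fdr = 0.05, requireFdr = FALSE, minPM = 3,
                        requireDirection = TRUE) {
    results <- lapply(comparisons, function(cmp)
        comparisonDegs(cmp$expr, cmp$mutant, cmp$control,
                       fcThreshold = fcThreshold, fdr = fdr,
                       requireFdr = requireFdr, minPM = minPM))
    entities <- intersectComparisons(results, requireDirection)
    genes <- collapseToGenes(entities, annotation, results)
    list(per_comparison = results, entities = entities, genes = genes)
}
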