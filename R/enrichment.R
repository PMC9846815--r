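# Over-representation analysis: observed/expected category overlap with
# upper-tail hypergeometric p-values and BH correction.

#' Category over-representation test
#'
#' For each category, counts the observed overlap k with the input list,
#' the expected count \eqn{e = m \cdot n / N} (m genes of the category in
#' the reference, n input genes, N reference genes), the fold enrichment
#' \eqn{f = k / e}, the upper-tail hypergeometric p-value
#' \eqn{P(X \ge k)} and the BH q-value across the tested categories.
#'
#' @param inputGenes Character vector of input gene ids (non-empty; must
#'   be drawn from the reference universe).
#' @param categoryMap data.frame with columns gene_id, category; a gene
#'   may belong to several (possibly overlapping) categories.
#' @param referenceSize Total number N of genes in the reference list
#'   (e.g. 21997 for a whole-transcriptome mouse array annotation); must
#'   be at least the largest category and the input size.
#' @return data.frame with columns category, reference_count, observed,
#'   expected, fold_enrichment, p_raw, q, ordered by p_raw.
#' @export
#' @examples
#' cm <- data.frame(gene_id = c(paste0("g", 1:20)),
#'                  category = "membrane")
#' overrepresentationTest(paste0("g", c(1:6, 50:53)), cm, referenceSize = 100)
overrepresentationTest <- function(inputGenes, categoryMap, referenceSize) {
    stopifnot(all(c("gene_id", "category") %in% colnames(categoryMap)),
              referenceSize >= 1)
    inputGenes <- unique(as.character(inputGenes))
    if (!length(inputGenes)) stop("empty input gene list")
    n <- length(inputGenes)
    if (n > referenceSize) stop("input larger than the reference list")
    cats <- split(unique(categoryMap[, c("gene_id", "category")])$gene_id,
                  unique(categoryMap[, c("gene_id", "category")])$category)
    m <- lengths(cats)
    if (any(m > referenceSize))
        stop("category larger than the reference list")
    k <- vapply(cats, function(g) length(intersect(inputGenes, g)),
                integer(1))
    e <- m * n / referenceSize
    f <- ifelse(e > 0, k / e, NA_real_)
    p <- phyper(k - 1, m, referenceSize - m, n, lower.tail = FALSE)
    out <- data.frame(category = names(cats),
                      reference_count = as.integer(m),
                      observed = as.integer(k),
                      expected = e,
                      fold_enrichment = f,
                      p_raw = p,
                      q = bhAdjust(p),
                      row.names = NULL)
    out[order(out$p_raw, -out$fold_enrichment), , drop = FALSE]
}
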