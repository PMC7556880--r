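#' @importFrom stats phyper
NULL

#' Read a differential-expression table
#'
#' @param path TSV with header columns gene_id, log2fc, p_adj.
#' @return data.frame with those columns; gene ids must be unique and p_adj
#'   in [0, 1].
#' @export
readExprTable <- function(path) {
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
        stringsAsFactors = FALSE)
    need <- c("gene_id", "log2fc", "p_adj")
    if (!all(need %in% names(tab)))
        stop("expression table must have columns: ",
            paste(need, collapse = ", "))
    if (anyDuplicated(tab$gene_id))
        stop("gene_id values must be unique")
    if (any(tab$p_adj < 0 | tab$p_adj > 1))
        stop("p_adj must lie in [0, 1]")
    tab[need]
}

#' Filter a DE table at fold-change and adjusted-p thresholds
#'
#' Keeps genes with |fold change| strictly greater than `fcThresh` (i.e.
#' \code{|log2fc| > log2(fcThresh)}) and adjusted p strictly below `pThresh`;
#' both inequalities strict.
#'
#' @param table data.frame with gene_id, log2fc, p_adj.
#' @param fcThresh linear fold-change threshold (default 1.5).
#' @param pThresh adjusted-p threshold (default 0.05).
#' @return data.frame of the retained rows plus a `sign` column (+1/-1).
#' @export
deFilter <- function(table, fcThresh = 1.5, pThresh = 0.05) {
    if (fcThresh <= 0 || pThresh <= 0)
        stop("thresholds must be positive")
    keep <- abs(table$log2fc) > log2(fcThresh) & table$p_adj < pThresh
    out <- table[keep, , drop = FALSE]
    out$sign <- sign(out$log2fc)
    rownames(out) <- NULL
    out
}

#' Hypergeometric overlap of two gene sets
#'
#' Exact upper-tail hypergeometric probability of observing at least the seen
#' overlap when `a` and `b` are drawn independently from the universe.
#'
#' @param a,b character vectors of gene ids, subsets of `universe`.
#' @param universe character vector of all eligible gene ids.
#' @return list with n_universe, n_a, n_b, n_overlap, p_hyper and jaccard.
#' @export
hypergeometricOverlap <- function(a, b, universe) {
    a <- unique(a); b <- unique(b); universe <- unique(universe)
    if (!all(a %in% universe) || !all(b %in% universe))
        stop("'a' and 'b' must be subsets of the universe")
    nU <- length(universe); nA <- length(a); nB <- length(b)
    nOv <- length(intersect(a, b))
    list(n_universe = nU, n_a = nA, n_b = nB, n_overlap = nOv,
        p_hyper = stats::phyper(nOv - 1, nA, nU - nA, nB,
            lower.tail = FALSE),
        jaccard = if (length(union(a, b))) nOv / length(union(a, b)) else 0)
}

#' Direction concordance of shared DE genes between two tables
#'
#' @param a,b DE data.frames (gene_id, log2fc, p_adj).
#' @param genes gene ids shared between both tables to evaluate.
#' @return named fractions up_up, down_down, discordant (summing to 1).
#' @export
directionConcordance <- function(a, b, genes) {
    genes <- unique(genes)
    missA <- setdiff(genes, a$gene_id)
    missB <- setdiff(genes, b$gene_id)
    if (length(missA) || length(missB))
        stop("gene(s) missing from a table: ",
            paste(utils::head(c(missA, missB), 5L), collapse = ", "))
    if (!length(genes))
        stop("empty gene set")
    sa <- sign(a$log2fc[match(genes, a$gene_id)])
    sb <- sign(b$log2fc[match(genes, b$gene_id)])
    c(up_up = mean(sa > 0 & sb > 0),
        down_down = mean(sa < 0 & sb < 0),
        discordant = mean(sa * sb <= 0))
}

#' Count DE genes by associated peak class
#'
#' A DE gene is counted once per category even when it is near several peaks
#' of that category.
#'
#' @param deGenes character vector of DE gene ids.
#' @param peakGenes data.frame with columns peak, gene_id mapping peaks to
#'   their (nearest) genes; a peak may map to several genes and vice versa.
#' @param peakClasses named character vector, peak -> class label (e.g. cGBM /
#'   dGBM / neither, or factor-alone vs overlap categories).
#' @return list with `counts` (named integer per class) and `genes` (list of
#'   DE gene ids per class).
#' @export
deCountsByPeakClass <- function(deGenes, peakGenes, peakClasses) {
    bad <- setdiff(unique(peakGenes$peak), names(peakClasses))
    if (length(bad))
        stop("peak(s) without a class label: ",
            paste(utils::head(bad, 5L), collapse = ", "))
    cls <- unique(unname(peakClasses))
    hits <- peakGenes[peakGenes$gene_id %in% deGenes, , drop = FALSE]
    hitCls <- peakClasses[hits$peak]
    genes <- lapply(stats::setNames(cls, cls), function(k)
        sort(unique(hits$gene_id[hitCls == k])))
    list(counts = vapply(genes, length, 1L), genes = genes)
}
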