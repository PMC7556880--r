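#' @importFrom stats pnorm sd
NULL

# assemble an EnrichResult from an observed statistic and a null sample
.enrichResult <- function(observed, nullCounts, nPerm, seed) {
    m <- mean(nullCounts)
    s <- stats::sd(nullCounts)
    z <- if (s > 0) (observed - m) / s else
        if (observed > m) Inf else if (observed < m) -Inf else 0
    new("EnrichResult",
        observed = as.numeric(observed),
        nullMean = m,
        nullSd = s,
        fold = if (m > 0) observed / m else 0,
        z = z,
        pEmpirical = (1 + sum(nullCounts >= observed)) / (1 + nPerm),
        pNormal = stats::pnorm(z, lower.tail = FALSE),
        nPerm = as.integer(nPerm),
        seed = as.integer(seed))
}

#' Permutation test for peak-set co-occupancy
#'
#' Tests whether the peaks of `a` overlap the peaks of `b` more often than
#' expected by chance.  The observed statistic is the number of `a` peaks
#' overlapping `b` by at least 1 bp (each `a` peak counted once).  The null
#' relocates every `a` peak uniformly at random within its own chromosome,
#' preserving its length, and recounts.  Fold enrichment, a z score, the
#' empirical p-value \code{(1 + #null >= obs) / (1 + nPerm)} and the upper
#' normal-tail p-value (which can express significance beyond the Monte-Carlo
#' floor) are all reported.
#'
#' @param a,b `GRanges` peak sets on `chroms`.
#' @param chroms `Seqinfo` chromosome table covering both sets.
#' @param nPerm number of permutations (>= 100).
#' @param seed RNG seed.
#' @return an [EnrichResult-class].
#' @export
permutationOverlapTest <- function(a, b, chroms, nPerm = 1000L, seed = 1L) {
    nPerm <- assertCount(nPerm, "nPerm", min = 100L)
    if (!length(a))
        stop("'a' is empty")
    chrA <- as.character(seqnames(a))
    missing <- setdiff(unique(chrA), seqlevels(chroms))
    if (length(missing))
        stop("chromosome(s) of 'a' absent from the chromosome table: ",
            paste(missing, collapse = ", "))
    observed <- sum(countOverlaps(a, b, ignore.strand = TRUE) > 0L)

    # merged b intervals per chromosome as 0-based half-open endpoints
    bm <- reduce(GRanges(seqnames(b), IRanges(start(b), end(b)),
        seqinfo = seqinfo(b)), ignore.strand = TRUE)
    bChrom <- as.character(seqnames(bm))
    set.seed(as.integer(seed))
    nullCounts <- numeric(nPerm)
    for (chr in unique(chrA)) {
        idx <- which(chrA == chr)
        lens <- width(a)[idx]
        L <- seqlengths(chroms)[[chr]]
        if (any(lens > L))
            stop("peak longer than its chromosome: ", chr)
        ms <- start(bm)[bChrom == chr] - 1L  # bed starts
        me <- end(bm)[bChrom == chr]         # bed ends
        nStart <- L - lens + 1L  # valid bed starts 0..L-len
        # starts matrix: peaks x perms, drawn uniformly
        starts <- matrix(floor(stats::runif(length(idx) * nPerm) *
            rep(nStart, nPerm)), nrow = length(idx))
        if (!length(ms))
            next
        # peak [s, s+len) overlaps some merged interval iff the last interval
        # starting before s+len (if any) ends after s
        sEnd <- starts + lens
        j <- matrix(findInterval(as.vector(sEnd) - 0.5, ms),
            nrow = length(idx))
        hit <- j > 0L
        hit[hit] <- me[j[hit]] > starts[hit]
        nullCounts <- nullCounts + colSums(hit)
    }
    .enrichResult(observed, nullCounts, nPerm, seed)
}

#' Permutation enrichment of a gene set among peak-proximal genes
#'
#' Tests whether a gene set (e.g. single-cell cluster markers) intersects the
#' genes proximal to a class of peaks more than random gene sets of the same
#' size drawn from the universe without replacement.
#'
#' @param geneSet character vector of gene ids (subset of `universe`).
#' @param proximalGenes character vector of gene ids near the peak class.
#' @param universe character vector of all eligible gene ids.
#' @param nPerm number of permutations (>= 100).
#' @param seed RNG seed.
#' @return an [EnrichResult-class]; `observed` is
#'   \code{length(intersect(geneSet, proximalGenes))}.
#' @export
genesetProximityEnrichment <- function(geneSet, proximalGenes, universe,
        nPerm = 1000L, seed = 1L) {
    nPerm <- assertCount(nPerm, "nPerm", min = 100L)
    geneSet <- unique(geneSet)
    proximalGenes <- unique(proximalGenes)
    universe <- unique(universe)
    if (length(geneSet) > length(universe))
        stop("gene set larger than the universe")
    if (!all(geneSet %in% universe) || !all(proximalGenes %in% universe))
        stop("gene set and proximal genes must be subsets of the universe")
    observed <- length(intersect(geneSet, proximalGenes))
    isProx <- universe %in% proximalGenes
    m <- length(geneSet)
    set.seed(as.integer(seed))
    nullCounts <- vapply(seq_len(nPerm), function(i)
        sum(isProx[sample.int(length(universe), m)]), numeric(1))
    .enrichResult(observed, nullCounts, nPerm, seed)
}
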