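#' @importFrom stats p.adjust rmultinom
NULL

#' Enumerate GBM / E-box composite sites within peaks
#'
#' For every PWM hit (GBM) and every E-box in the same peak whose signed
#' edge-to-edge gap lies within `window`, one pair is emitted.  The gap is
#' positive when the E-box starts after the GBM ends, negative when the E-box
#' ends before the GBM starts, and 0 when the two footprints overlap.
#' Orientation is the strand of the GBM hit (the E-box pattern is strandless).
#'
#' @param seqs named `DNAStringSet` (or character vector) of peak sequences.
#' @param pwm a [PWMatrix-class].
#' @param threshold fraction-of-maximum threshold for GBM hits.
#' @param window maximum absolute gap in bp (default 100).
#' @return list with `pairs` (data.frame: peak, gbm_offset, gbm_strand,
#'   ebox_offset, gap, orientation) and `nPeaksWithPair`.
#' @export
compositeSites <- function(seqs, pwm = gbmMatrix(), threshold = 0.8,
        window = 100L) {
    window <- assertCount(window, "window")
    nm <- if (is.null(names(seqs))) paste0("peak_", seq_along(seqs)) else
        names(seqs)
    L <- nrow(pwm@probs)
    rows <- vector("list", length(seqs))
    for (i in seq_along(seqs)) {
        s <- as.character(seqs[[i]])
        hits <- scanPWM(s, pwm, threshold = threshold)
        if (!nrow(hits))
            next
        eb <- findEbox(s)
        if (!nrow(eb))
            next
        grid <- expand.grid(h = seq_len(nrow(hits)), e = seq_len(nrow(eb)))
        gStart <- hits$offset[grid$h]
        gEnd <- gStart + L
        eStart <- eb$offset[grid$e]
        eEnd <- eStart + 6L
        gap <- ifelse(eStart >= gEnd, eStart - gEnd,
            ifelse(eEnd <= gStart, eEnd - gStart, 0L))
        keep <- abs(gap) <= window
        if (!any(keep))
            next
        rows[[i]] <- data.frame(peak = nm[i],
            gbm_offset = gStart[keep],
            gbm_strand = hits$strand[grid$h][keep],
            ebox_offset = eStart[keep],
            gap = as.integer(gap[keep]),
            orientation = paste0("GBM", hits$strand[grid$h][keep]),
            stringsAsFactors = FALSE)
    }
    pairs <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
    if (is.null(pairs))
        pairs <- data.frame(peak = character(0), gbm_offset = integer(0),
            gbm_strand = character(0), ebox_offset = integer(0),
            gap = integer(0), orientation = character(0),
            stringsAsFactors = FALSE)
    list(pairs = pairs, nPeaksWithPair = length(unique(pairs$peak)))
}

#' Tabulate composite-site configurations into a spacing grid
#'
#' @param pairs the `pairs` data.frame from [compositeSites()] (or the list
#'   itself).
#' @param window maximum absolute gap (default 100); pairs outside it error.
#' @return a [PairGrid-class] of counts over orientation x gap.
#' @export
spacingGrid <- function(pairs, window = 100L) {
    window <- assertCount(window, "window")
    nPeaks <- 0L
    if (is.list(pairs) && !is.data.frame(pairs)) {
        nPeaks <- pairs$nPeaksWithPair
        pairs <- pairs$pairs
    } else if (nrow(pairs)) {
        nPeaks <- length(unique(pairs$peak))
    }
    gaps <- seq(-window, window)
    counts <- matrix(0L, nrow = 2L, ncol = length(gaps),
        dimnames = list(c("GBM+", "GBM-"), as.character(gaps)))
    if (nrow(pairs)) {
        if (any(abs(pairs$gap) > window))
            stop("pair gap outside the grid window")
        tab <- table(factor(pairs$orientation, c("GBM+", "GBM-")),
            factor(pairs$gap, gaps))
        counts[] <- as.integer(tab)
    }
    new("PairGrid", counts = counts, window = window,
        total = sum(counts), nPeaksWithPair = as.integer(nPeaks))
}

#' Most frequent spacing/orientation configuration
#'
#' @param grid a [PairGrid-class] with at least one pair.
#' @return list with `orientation`, `gap`, `fraction`; ties are broken by
#'   orientation order (GBM+ first), then smaller |gap|, then positive gap.
#' @export
maxConfigFraction <- function(grid) {
    if (grid@total == 0L)
        stop("empty grid")
    cnt <- grid@counts
    gaps <- as.integer(colnames(cnt))
    cand <- which(cnt == max(cnt), arr.ind = TRUE)
    o <- order(cand[, "row"], abs(gaps[cand[, "col"]]),
        -sign(gaps[cand[, "col"]]))
    best <- cand[o[1L], ]
    list(orientation = rownames(cnt)[best["row"]],
        gap = gaps[best["col"]],
        fraction = cnt[best["row"], best["col"]] / grid@total)
}

#' Per-configuration enrichment against a uniform multinomial null
#'
#' Draws `nPerm` multinomial grids with uniform cell probabilities conditioned
#' on the observed total, computes a per-cell upper-tail empirical p-value and
#' adjusts across cells by Benjamini-Hochberg.
#'
#' @param grid a [PairGrid-class].
#' @param nPerm number of null draws (>= 100).
#' @param seed RNG seed.
#' @return data.frame in long format: orientation, gap, count, fraction, p,
#'   p_adj.
#' @export
configEnrichmentTest <- function(grid, nPerm = 1000L, seed = 1L) {
    nPerm <- assertCount(nPerm, "nPerm", min = 100L)
    if (grid@total < 1L)
        stop("empty grid")
    cnt <- grid@counts
    nCell <- length(cnt)
    obs <- as.vector(cnt)
    set.seed(as.integer(seed))
    nulls <- stats::rmultinom(nPerm, grid@total, rep(1 / nCell, nCell))
    exceed <- rowSums(nulls >= obs)  # row i: cell i across draws
    p <- (1 + exceed) / (1 + nPerm)
    out <- data.frame(
        orientation = rep(rownames(cnt), times = ncol(cnt)),
        gap = rep(as.integer(colnames(cnt)), each = nrow(cnt)),
        count = obs,
        fraction = if (grid@total > 0L) obs / grid@total else 0,
        p = p,
        p_adj = stats::p.adjust(p, method = "BH"),
        stringsAsFactors = FALSE)
    out[order(out$gap, out$orientation), ]
}
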