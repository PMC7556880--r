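#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#'   matchPattern vcountPattern oligonucleotideFrequency mkAllStrings
NULL

#' Construct a PWMatrix from position probabilities
#'
#' Rows must sum to ~1 before the pseudocount is applied; the pseudocount is
#' added to every cell and rows renormalised, after which per-position
#' log-odds against a uniform background and the achievable score range are
#' derived.
#'
#' @param probs numeric L x 4 matrix of base probabilities, columns in
#'   A, C, G, T order (column names optional).
#' @param motifID motif identifier.
#' @param pseudocount pseudocount (default 1e-3).
#' @return a [PWMatrix-class].
#' @examples
#' onehot <- diag(4)[match(strsplit("GACCACCC", "")[[1]], c("A","C","G","T")), ]
#' pwm <- pwMatrix(onehot, "toy")
#' @export
pwMatrix <- function(probs, motifID = "pwm", pseudocount = 1e-3) {
    probs <- as.matrix(probs)
    if (ncol(probs) != 4L)
        stop("'probs' must have 4 columns (A, C, G, T)")
    if (nrow(probs) < 4L)
        stop("motif must have at least 4 positions")
    if (any(abs(rowSums(probs) - 1) > 0.01))
        stop("each position must sum to ~1 before pseudocounting (row ",
            which(abs(rowSums(probs) - 1) > 0.01)[1L], " does not)")
    probs <- probs + pseudocount
    probs <- probs / rowSums(probs)
    dimnames(probs) <- list(NULL, BASES)
    lo <- log(probs / 0.25)
    new("PWMatrix", motifID = as.character(motifID), probs = probs,
        pseudocount = pseudocount, logOdds = lo,
        scoreMin = sum(apply(lo, 1, min)), scoreMax = sum(apply(lo, 1, max)))
}

#' Read a PWM text file
#'
#' Accepts either the bundled dialect (a `>motif_id` header followed by one
#' line of four whitespace-separated probabilities per position, A C G T
#' order) or a headerless L x 4 table, in which case the motif id is the file
#' base name.
#'
#' @param path PWM text file.
#' @param pseudocount passed to [pwMatrix()].
#' @return a [PWMatrix-class].
#' @export
readPWM <- function(path, pseudocount = 1e-3) {
    lines <- trimws(readLines(path))
    lines <- lines[nzchar(lines)]
    if (!length(lines))
        stop("empty PWM file: ", path)
    if (startsWith(lines[1L], ">")) {
        id <- sub("^>\\s*", "", lines[1L])
        lines <- lines[-1L]
    } else {
        id <- tools::file_path_sans_ext(basename(path))
        # tolerate a Cis-BP style header row of base letters
        if (grepl("[ACGTacgt]", lines[1L]) &&
            !grepl("[0-9]", lines[1L]))
            lines <- lines[-1L]
    }
    rows <- lapply(lines, function(l)
        suppressWarnings(as.numeric(strsplit(l, "\\s+")[[1L]])))
    # Cis-BP tables carry a leading position index column; drop it
    rows <- lapply(rows, function(r) if (length(r) == 5L) r[-1L] else r)
    if (any(vapply(rows, length, 1L) != 4L) || anyNA(unlist(rows)))
        stop("malformed PWM row in ", path)
    pwMatrix(do.call(rbind, rows), motifID = id, pseudocount = pseudocount)
}

#' @rdname readPWM
#' @param pwm a `PWMatrix`; `writePWM` emits the probabilities before
#'   pseudocounting cannot be undone, so it writes the stored (pseudocounted,
#'   renormalised) matrix.
#' @export
writePWM <- function(pwm, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0(">", pwm@motifID), con)
    utils::write.table(format(pwm@probs, digits = 6, trim = TRUE), con,
        sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' The bundled canonical Gli-binding-motif matrix
#'
#' A synthetic position probability matrix with consensus GACCACCC, built to
#' mirror the salient feature of published canonical Gli matrices: position 5
#' (the highly constrained 'A') is near-one-hot (0.97) while the remaining
#' positions are soft (0.70 on the consensus base).  Under the default 0.8
#' fraction-of-maximum threshold the divergent 8-mer GACCTCCC scores ~0.75
#' (below threshold) while any single mismatch at a soft position still
#' scores ~0.89 (above threshold).  It is a stand-in, not a database matrix.
#'
#' @param pseudocount passed to [readPWM()].
#' @return a [PWMatrix-class].
#' @export
gbmMatrix <- function(pseudocount = 1e-3) {
    readPWM(system.file("extdata", "gbm_synthetic.pwm", package = "comotif",
        mustWork = TRUE), pseudocount = pseudocount)
}

# score every window of `codes` (integer-coded sequence) under `lo`
.scanOneStrand <- function(codes, lo) {
    L <- nrow(lo)
    nw <- length(codes) - L + 1L
    if (nw < 1L)
        return(numeric(0))
    idx <- outer(seq_len(nw) - 1L, seq_len(L), "+")
    S <- vapply(seq_len(L), function(p) {
        unname(lo[p, ])[codes[idx[, p]]]
    }, numeric(nw))
    if (nw == 1L) sum(S) else rowSums(S)
}

#' Scan a sequence with a PWM at a fraction-of-maximum threshold
#'
#' Every window on both strands is scored by summed log-odds and normalised to
#' \code{(raw - scoreMin) / (scoreMax - scoreMin)}; windows containing N are
#' skipped.  For a degenerate matrix with zero score range every window's
#' normalised score is defined as 1.
#'
#' @param seq a DNA string (character or `DNAString`).
#' @param pwm a [PWMatrix-class].
#' @param threshold minimum normalised score to report (default 0.8, the
#'   conventional "80% match" call).
#' @param returnAll report every scored window instead of thresholded hits.
#' @return data.frame with columns offset (0-based within `seq`), strand,
#'   score (raw log-odds), normScore.
#' @export
scanPWM <- function(seq, pwm, threshold = 0.8, returnAll = FALSE) {
    assertFraction(threshold, "threshold")
    codes <- dnaCodes(as.character(seq))
    lo <- pwm@logOdds
    L <- nrow(lo)
    loRC <- lo[L:1, c(4L, 3L, 2L, 1L), drop = FALSE]
    colnames(loRC) <- BASES
    fwd <- .scanOneStrand(codes, lo)
    rev <- .scanOneStrand(codes, loRC)
    rng <- pwm@scoreMax - pwm@scoreMin
    normalise <- function(x) {
        if (rng < 1e-12) ifelse(is.na(x), NA_real_, 1) else
            (x - pwm@scoreMin) / rng
    }
    out <- data.frame(
        offset = c(seq_along(fwd), seq_along(rev)) - 1L,
        strand = rep(c("+", "-"), c(length(fwd), length(rev))),
        score = c(fwd, rev),
        normScore = c(normalise(fwd), normalise(rev)),
        stringsAsFactors = FALSE)
    out <- out[!is.na(out$normScore), , drop = FALSE]
    if (!returnAll)
        out <- out[out$normScore >= threshold, , drop = FALSE]
    out <- out[order(out$offset, out$strand), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Find E-box (CANNTG) matches
#'
#' Reports every offset whose window has C,A at positions 1-2 and T,G at
#' positions 5-6.  CANNTG is its own reverse-complement pattern, so each site
#' is reported once and no strand is attached.
#'
#' @param seq DNA string.
#' @return data.frame with columns offset (0-based) and match (the 6-mer).
#' @export
findEbox <- function(seq) {
    subject <- DNAString(as.character(seq))
    m <- matchPattern("CANNTG", subject,
        fixed = c(pattern = FALSE, subject = TRUE))
    data.frame(offset = BiocGenerics::start(m) - 1L,
        match = as.character(m), stringsAsFactors = FALSE)
}

#' Find core matches on both strands
#'
#' All forward-strand matches of `core` and of its reverse complement, with
#' overlapping matches all reported.  The default CCTCC core is the minimal
#' divergent Gli-binding-motif signature.
#'
#' @param seq DNA string.
#' @param core core sequence (default "CCTCC").
#' @return data.frame with columns offset (0-based) and strand.
#' @export
findCore <- function(seq, core = "CCTCC") {
    if (!nzchar(core))
        stop("'core' must be non-empty")
    subject <- DNAString(as.character(seq))
    fwd <- BiocGenerics::start(matchPattern(core, subject)) - 1L
    rcCore <- revcomp(core)
    rev <- if (rcCore == core) integer(0) else
        BiocGenerics::start(matchPattern(rcCore, subject)) - 1L
    out <- data.frame(
        offset = c(fwd, rev),
        strand = rep(c("+", "-"), c(length(fwd), length(rev))),
        stringsAsFactors = FALSE)
    out <- out[order(out$offset, out$strand), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Classify one peak sequence by Gli-binding-motif content
#'
#' Exhaustive and mutually exclusive three-way rule: \code{cGBM} iff at least
#' one PWM hit at `threshold`; else \code{dGBM} iff at least one core match on
#' either strand; else \code{neither}.
#'
#' @param seq DNA string.
#' @param pwm a [PWMatrix-class] (default the bundled canonical GBM matrix).
#' @param threshold fraction-of-maximum threshold (default 0.8).
#' @param core divergent-motif core (default "CCTCC").
#' @return list with `class` (one of cGBM/dGBM/neither), `hits` (PWM hit
#'   table) and `cores` (core match table).
#' @export
classifyPeak <- function(seq, pwm = gbmMatrix(), threshold = 0.8,
        core = "CCTCC") {
    hits <- scanPWM(seq, pwm, threshold = threshold)
    cores <- findCore(seq, core = core)
    cls <- if (nrow(hits)) "cGBM" else if (nrow(cores)) "dGBM" else "neither"
    list(class = cls, hits = hits, cores = cores)
}

#' Classify a peak set and report class fractions
#'
#' @param seqs named `DNAStringSet` (or character vector) of peak sequences.
#' @inheritParams classifyPeak
#' @return list with `fractions` (named cGBM/dGBM/neither, summing to 1) and
#'   `table` (one row per peak: peak, class, nHits, nCores).
#' @export
classifyPeakSet <- function(seqs, pwm = gbmMatrix(), threshold = 0.8,
        core = "CCTCC") {
    if (!length(seqs))
        stop("empty peak set")
    nm <- if (is.null(names(seqs))) paste0("peak_", seq_along(seqs)) else
        names(seqs)
    rows <- lapply(seq_along(seqs), function(i) {
        cl <- classifyPeak(as.character(seqs[[i]]), pwm,
            threshold = threshold, core = core)
        data.frame(peak = nm[i], class = cl$class, nHits = nrow(cl$hits),
            nCores = nrow(cl$cores), stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    counts <- vapply(c("cGBM", "dGBM", "neither"),
        function(k) sum(tab$class == k), 1L)
    list(fractions = counts / length(seqs), table = tab)
}

#' Canonical representative of a k-mer
#'
#' The lexicographic minimum of a k-mer and its reverse complement; a
#' palindromic k-mer is its own representative.
#'
#' @param kmer DNA string over A,C,G,T.
#' @return canonical k-mer string (vectorised).
#' @examples
#' canonicalKmer("TTTTTTTT")  # "AAAAAAAA"
#' @export
canonicalKmer <- function(kmer) {
    kmer <- toupper(kmer)
    if (any(grepl("[^ACGT]", kmer)))
        stop("k-mer contains an ambiguous base")
    rc <- revcomp(kmer)
    ifelse(kmer <= rc, kmer, rc)
}

#' Number (and optionally list) of canonical k-mers
#'
#' With P palindromic (self-reverse-complement) k-mers — 0 for odd k,
#' \code{4^(k/2)} for even k — there are \code{(4^k - P)/2 + P} canonical
#' k-mers; for k = 8 this is 32,896.
#'
#' @param k word size, 1..12 (listing restricted to k <= 10).
#' @param list also return the sorted canonical k-mer strings.
#' @return the count, or (with `list = TRUE`) a list with `count` and `kmers`.
#' @export
enumerateCanonicalKmers <- function(k, list = FALSE) {
    k <- assertCount(k, "k")
    if (k > 12L)
        stop("'k' must be between 1 and 12")
    P <- if (k %% 2L == 0L) 4^(k / 2) else 0
    count <- (4^k - P) / 2 + P
    if (!list)
        return(count)
    if (k > 10L)
        stop("listing canonical k-mers is supported for k <= 10")
    all <- mkAllStrings(BASES, width = k)
    rc <- revcompFixed(all, k)
    kmers <- sort(unique(ifelse(all <= rc, all, rc)), method = "radix")
    stopifnot(length(kmers) == count)
    list(count = count, kmers = kmers)
}

#' Canonical k-mer census of a sequence set
#'
#' Each window position of each sequence contributes exactly one count to its
#' canonical k-mer, so occurrences are counted on either strand while
#' palindromic windows are counted once, not twice.  Windows containing N are
#' skipped but still included in `totalPositions`.
#'
#' @param seqs `DNAStringSet` or character vector.
#' @param k word size (default 8).
#' @return a [KmerCensus-class] storing the observed canonical k-mers.
#' @export
countKmers <- function(seqs, k = 8L) {
    k <- assertCount(k, "k")
    if (k > 12L)
        stop("'k' must be between 1 and 12")
    seqs <- DNAStringSet(seqs)
    fwd <- oligonucleotideFrequency(seqs, width = k,
        simplify.as = "collapsed")
    nm <- names(fwd)
    rc <- revcompFixed(nm, k)
    canon <- ifelse(nm <= rc, nm, rc)
    agg <- rowsum(as.numeric(fwd), canon)
    counts <- as.integer(agg[, 1L])
    names(counts) <- rownames(agg)
    counts <- counts[counts > 0L]
    counts <- counts[order(names(counts), method = "radix")]
    new("KmerCensus", k = k, counts = counts,
        totalPositions = sum(pmax(0, BiocGenerics::width(seqs) - k + 1)))
}

#' Rank of a k-mer within a census
#'
#' Competition ranking by descending count with ties broken by ascending
#' k-mer string; a k-mer absent from the census ranks immediately after all
#' present ones.
#'
#' @param census a [KmerCensus-class].
#' @param kmer query k-mer (canonicalised internally).
#' @return 1-based rank.
#' @export
kmerRank <- function(census, kmer) {
    canon <- canonicalKmer(kmer)
    if (nchar(canon) != census@k)
        stop("query k-mer length does not match census k")
    cnt <- census@counts
    if (!length(cnt) || !canon %in% names(cnt))
        return(length(cnt) + 1L)
    ord <- order(-cnt, names(cnt), method = "radix")
    match(canon, names(cnt)[ord])
}

#' Fraction of peaks containing a k-mer on either strand
#'
#' Per-peak presence/absence (as opposed to the per-occurrence census of
#' [countKmers()]): the fraction of sequences containing at least one match of
#' the k-mer or its reverse complement.
#'
#' @param seqs `DNAStringSet` or character vector of peak sequences.
#' @param kmer query k-mer.
#' @return fraction in [0, 1].
#' @export
kmerPeakFraction <- function(seqs, kmer) {
    if (!length(seqs))
        stop("empty peak set")
    seqs <- DNAStringSet(seqs)
    kmer <- toupper(kmer)
    hit <- vcountPattern(kmer, seqs) > 0L
    rc <- revcomp(kmer)
    if (rc != kmer)
        hit <- hit | vcountPattern(rc, seqs) > 0L
    mean(hit)
}
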