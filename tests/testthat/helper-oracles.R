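# Independent oracles and small fixture builders used across the suite.
# Oracles deliberately avoid the package's own code paths: reverse
# complements come from Biostrings, scores from per-column arithmetic,
# counting from plain dictionaries.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(Biostrings)
})

oracleRevcomp <- function(x) {
    as.character(reverseComplement(DNAString(x)))
}

# dictionary-based canonical k-mer census: enumerate every window string,
# reverse-complement it positionally, and tabulate — no collapsing trick
bfCountKmers <- function(seqs, k) {
    words <- unlist(lapply(as.character(seqs), function(s) {
        n <- nchar(s)
        if (n < k) return(character(0))
        substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
    }))
    words <- words[!grepl("[^ACGT]", words)]
    if (!length(words)) return(integer(0))
    rc <- vapply(strsplit(chartr("ACGT", "TGCA", words), "", fixed = TRUE),
        function(ch) paste(rev(ch), collapse = ""), character(1))
    canon <- ifelse(words <= rc, words, rc)
    tab <- table(canon)
    cnt <- as.integer(tab)
    names(cnt) <- names(tab)
    cnt[order(names(cnt), method = "radix")]
}

# per-column log-odds score of one window under a PWMatrix (oracle for
# scanPWM's raw score)
oracleScore <- function(pwm, word) {
    lo <- pwm@logOdds
    sum(vapply(seq_len(nchar(word)), function(p)
        lo[p, substr(word, p, p)], numeric(1)))
}

# exhaustive nearest-TSS scan (oracle for nearestGenes)
bfNearest <- function(bedStart, bedEnd, tss, ids) {
    inside <- which(tss >= bedStart & tss < bedEnd)
    if (length(inside)) {
        g <- min(ids[inside])
        return(list(up = g, upD = 0, dn = g, dnD = 0))
    }
    up <- which(tss <= bedStart)
    dn <- which(tss >= bedEnd)
    pick <- function(cand, d) {
        keep <- cand[d[cand] == min(d[cand])]
        keep[order(ids[keep])][1L]
    }
    res <- list(up = NA, upD = NA, dn = NA, dnD = NA)
    if (length(up)) {
        k <- pick(up, bedStart - tss)
        res$up <- ids[k]; res$upD <- bedStart - tss[k]
    }
    if (length(dn)) {
        k <- pick(dn, tss - bedEnd)
        res$dn <- ids[k]; res$dnD <- tss[k] - bedEnd
    }
    res
}

# uniform random peaks on a Seqinfo, all the same length
randomPeaks <- function(n, len, chroms) {
    L <- GenomeInfoDb::seqlengths(chroms)
    chr <- sample(GenomeInfoDb::seqlevels(chroms), n, replace = TRUE,
        prob = L / sum(L))
    s <- floor(runif(n) * (L[chr] - len + 1))
    GRanges(chr, IRanges(s + 1, width = len), seqinfo = chroms)
}

# expected null overlap count for uniformly relocated peaks: per peak, the
# fraction of valid starts falling in the union of per-interval hit zones
oracleNullMean <- function(aLens, aChroms, b, chroms) {
    bChr <- as.character(seqnames(b))
    total <- 0
    for (i in seq_along(aLens)) {
        len <- aLens[i]
        L <- GenomeInfoDb::seqlengths(chroms)[[aChroms[i]]]
        bs <- start(b)[bChr == aChroms[i]] - 1
        be <- end(b)[bChr == aChroms[i]]
        if (!length(bs)) next
        zs <- pmax(0, bs - len + 1)
        ze <- pmin(L - len, be - 1)
        keep <- ze >= zs
        zones <- IRanges(zs[keep] + 1, ze[keep] + 1)  # starts, shifted
        hit <- sum(width(reduce(zones)))
        total <- total + hit / (L - len + 1)
    }
    total
}

# exact upper-tail hypergeometric by explicit summation
oracleHyper <- function(nU, nA, nB, nOv) {
    ks <- seq(nOv, min(nA, nB))
    sum(choose(nA, ks) * choose(nU - nA, nB - ks)) / choose(nU, nB)
}

writeTempBed <- function(lines) {
    f <- tempfile(fileext = ".bed")
    writeLines(lines, f)
    f
}
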