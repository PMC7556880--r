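si <- chromTable(c("chr1", "chr2"), c(10000L, 8000L))

test_that("BED parsing maps 0-based half-open coordinates and validates", {
    gr <- readPeaks(writeTempBed("chr1\t10\t20"), si)
    expect_equal(start(gr), 11L)
    expect_equal(end(gr), 20L)

    expect_error(readPeaks(writeTempBed("chr1\t20\t10"), si),
        "start >= end")
    expect_error(readPeaks(writeTempBed("chr1\t10"), si), "fewer than 3")
    expect_error(readPeaks(writeTempBed("chr1\tx\t20"), si), "non-numeric")

    unsorted <- readPeaks(writeTempBed(c("chr2\t5\t50", "chr1\t100\t200",
        "chr1\t5\t50")), si)
    expect_equal(as.character(seqnames(unsorted)), c("chr1", "chr1", "chr2"))
    expect_equal(start(unsorted), c(6L, 101L, 6L))
})

test_that("strict mode rejects and lenient mode skips off-table lines", {
    lines <- c("chr1\t0\t100", "chrX\t0\t100", "chr1\t9990\t10050")
    f <- writeTempBed(lines)
    expect_error(readPeaks(f, si, strict = TRUE), "outside chromosome table")
    expect_warning(gr <- readPeaks(f, si, strict = FALSE), "skipping")
    expect_length(gr, 1L)
})

test_that("BED round-trip is exact on coordinates, names and strands", {
    set.seed(42)
    n <- 100L
    gr <- randomPeaks(n, 50L, si)
    names(gr) <- sprintf("p%03d", seq_len(n))
    strand(gr) <- sample(c("+", "-", "*"), n, replace = TRUE)
    gr <- sort(gr, ignore.strand = TRUE)
    f <- tempfile(fileext = ".bed")
    writePeaks(gr, f)
    back <- readPeaks(f, si)
    expect_identical(start(back), start(gr))
    expect_identical(end(back), end(gr))
    expect_identical(names(back), names(gr))
    expect_identical(as.character(strand(back)), as.character(strand(gr)))

    f2 <- tempfile(fileext = ".bed")
    writePeaks(GRanges(seqinfo = si), f2)
    expect_length(readPeaks(f2, si), 0L)
})

test_that("replicate merging keeps only spans with enough support", {
    g <- function(s, e) GRanges("chr1", IRanges(s + 1, e), seqinfo = si)
    # identical single peaks
    m <- mergeReplicates(list(g(0, 100), g(0, 100)), minSupport = 2)
    expect_equal(start(m), 1L); expect_equal(end(m), 100L)
    # no sharing
    expect_length(mergeReplicates(list(g(0, 100), g(200, 300)), 2), 0L)
    # partial overlap merges to the union span
    m <- mergeReplicates(list(g(0, 100), g(50, 150)), 2)
    expect_equal(start(m), 1L); expect_equal(end(m), 150L)
    expect_error(mergeReplicates(list(g(0, 100)), 0), "integer >= 1")
    expect_error(mergeReplicates(list(g(0, 100)), 2), "exceeds")
})

test_that("replicate merging is idempotent on merged output", {
    set.seed(7)
    reps <- replicate(3, randomPeaks(80L, 120L, si), simplify = FALSE)
    m <- mergeReplicates(reps, 2)
    m2 <- mergeReplicates(list(m, m), 2)
    expect_identical(as.data.frame(m2), as.data.frame(m))
})

test_that("intersection counts a-peaks once and is monotone in b", {
    g <- function(...) {
        x <- matrix(c(...), ncol = 2, byrow = TRUE)
        GRanges("chr1", IRanges(x[, 1] + 1, x[, 2]), seqinfo = si)
    }
    a <- g(0, 10, 20, 30)
    expect_equal(intersectPeaks(a, a)$fracA, 1.0)
    bOther <- GRanges("chr2", IRanges(1, 100), seqinfo = si)
    expect_equal(intersectPeaks(a, bOther)$fracA, 0.0)
    res <- intersectPeaks(a, g(5, 8))
    expect_equal(res$fracA, 0.5)
    expect_equal(start(res$overlap), 1L)
    expect_error(intersectPeaks(a, a, minBp = 0), "integer >= 1")

    set.seed(11)
    for (i in 1:10) {
        aa <- randomPeaks(40L, 100L, si)
        b1 <- randomPeaks(20L, 100L, si)
        b2 <- c(b1, randomPeaks(20L, 100L, si))
        expect_gte(intersectPeaks(aa, b2)$fracA,
            intersectPeaks(aa, b1)$fracA)
    }
})

test_that("nearest-gene assignment handles containment and flanks", {
    mkGenes <- function(tss, ids) {
        gr <- GRanges("chr1", IRanges(tss + 1, tss + 100), strand = "+",
            seqinfo = si)
        mcols(gr)$gene_id <- ids
        mcols(gr)$tss <- as.integer(tss)
        gr
    }
    peak <- function(s, e) GRanges("chr1", IRanges(s + 1, e), seqinfo = si)

    res <- nearestGenes(peak(480, 520), mkGenes(500, "g1"))
    expect_equal(res$upstream_gene, "g1")
    expect_equal(res$downstream_gene, "g1")
    expect_equal(res$upstream_dist, 0)
    expect_equal(res$downstream_dist, 0)

    res <- nearestGenes(peak(400, 410), mkGenes(c(100, 900), c("g1", "g2")))
    expect_equal(res$upstream_gene, "g1")
    expect_equal(res$upstream_dist, 300)
    expect_equal(res$downstream_gene, "g2")
    expect_equal(res$downstream_dist, 490)

    res <- nearestGenes(peak(0, 10), mkGenes(c(100, 900), c("g1", "g2")))
    expect_true(is.na(res$upstream_gene))
    expect_equal(res$downstream_gene, "g1")

    # tss tie resolves to the smaller gene id
    res <- nearestGenes(peak(400, 410), mkGenes(c(100, 100), c("gB", "gA")))
    expect_equal(res$upstream_gene, "gA")

    expect_warning(
        nearestGenes(GRanges("chr2", IRanges(1, 10), seqinfo = si),
            mkGenes(100, "g1")), "no annotated gene")
})

test_that("nearest-gene assignment matches the all-pairs oracle", {
    set.seed(99)
    nG <- 100L
    tss <- sort(sample.int(9000L, nG))
    genes <- GRanges("chr1", IRanges(tss + 1, tss + 50), strand = "+",
        seqinfo = si)
    mcols(genes)$gene_id <- sprintf("g%03d", sample(nG))
    mcols(genes)$tss <- tss
    peaks <- randomPeaks(50L, 80L, chromTable("chr1", 10000L))
    res <- nearestGenes(peaks, genes)
    for (i in seq_along(peaks)) {
        o <- bfNearest(start(peaks)[i] - 1L, end(peaks)[i], tss,
            mcols(genes)$gene_id)
        expect_identical(res$upstream_gene[i], as.character(o$up))
        expect_identical(res$downstream_gene[i], as.character(o$dn))
        expect_equal(res$upstream_dist[i], as.numeric(o$upD))
        expect_equal(res$downstream_dist[i], as.numeric(o$dnD))
    }
})

test_that("peak sequences are forward-strand substrings with exact bounds", {
    store <- DNAStringSet(c(chr1 = "ACGTACGT"))
    siTiny <- chromTable("chr1", 8L)
    g <- function(s, e) GRanges("chr1", IRanges(s + 1, e), seqinfo = siTiny)
    expect_equal(as.character(peakSequences(g(0, 4), store)[[1]]), "ACGT")
    expect_equal(as.character(peakSequences(g(4, 8), store)[[1]]), "ACGT")
    expect_equal(as.character(peakSequences(g(2, 6), store)[[1]]), "GTAC")
    expect_error(peakSequences(
        GRanges("chr1", IRanges(7, 9)), store), "beyond")
    expect_error(peakSequences(
        GRanges("chrZ", IRanges(1, 4)), store), "absent")
})
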