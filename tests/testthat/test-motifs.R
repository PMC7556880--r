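pwm <- gbmMatrix()

test_that("PWM construction derives the score range correctly", {
    # degenerate uniform matrix: zero range, every window scores 1 by rule
    uni <- pwMatrix(matrix(0.25, nrow = 8, ncol = 4), "uniform")
    expect_equal(uni@scoreMin, uni@scoreMax)
    sc <- scanPWM("GACCACCCTTTT", uni, returnAll = TRUE)
    expect_true(all(sc$normScore == 1))

    # pseudocounted one-hot: closed-form maximum
    onehot <- diag(4)[match(strsplit("GACCACCC", "")[[1]],
        c("A", "C", "G", "T")), ]
    oh <- pwMatrix(onehot, "onehot")
    expect_equal(oh@scoreMax, 8 * log(((1 + 1e-3) / (1 + 4e-3)) / 0.25),
        tolerance = 1e-9)
    expect_equal(max(scanPWM("GACCACCC", oh, returnAll = TRUE)$normScore), 1)

    expect_error(pwMatrix(matrix(0.3, 8, 4)), "sum to ~1")
    expect_error(pwMatrix(matrix(0.25, 2, 4)), "at least 4 positions")
})

test_that("PWM text round-trips and the bundled matrix has the right shape", {
    expect_equal(motifID(pwm), "GBM_synthetic_GACCACCC")
    expect_equal(nrow(pwm@probs), 8L)
    expect_equal(rowSums(pwm@probs), rep(1, 8), tolerance = 1e-9)
    f <- tempfile(fileext = ".pwm")
    writePWM(pwm, f)
    back <- readPWM(f, pseudocount = 0)
    expect_equal(back@probs, pwm@probs, tolerance = 1e-4)
})

test_that("scanning finds the consensus on both strands at norm 1", {
    hits <- scanPWM("TTTGACCACCCTTT", pwm)
    expect_equal(nrow(hits), 1L)
    expect_equal(hits$offset, 3L)
    expect_equal(hits$strand, "+")
    expect_equal(hits$normScore, 1.0)

    rcHits <- scanPWM("TTTGGGTGGTCTTT", pwm)  # revcomp of consensus
    expect_equal(nrow(rcHits), 1L)
    expect_equal(rcHits$strand, "-")
    expect_equal(rcHits$normScore, 1.0)
})

test_that("raw window scores agree with the per-column oracle", {
    set.seed(3)
    for (word in c("GACCTCCC", "GACCACCC", "AAAAAAAA",
        vapply(1:20, function(i) paste(sample(c("A", "C", "G", "T"), 8,
            replace = TRUE), collapse = ""), character(1)))) {
        sc <- scanPWM(word, pwm, returnAll = TRUE)
        expect_equal(sc$score[sc$strand == "+"], oracleScore(pwm, word),
            tolerance = 1e-12)
        expect_equal(sc$score[sc$strand == "-"],
            oracleScore(pwm, oracleRevcomp(word)), tolerance = 1e-12)
    }
    # the divergent 8-mer scores below the 0.8 call threshold
    d <- (oracleScore(pwm, "GACCTCCC") - pwm@scoreMin) /
        (pwm@scoreMax - pwm@scoreMin)
    expect_lt(d, 0.8)
    expect_equal(max(scanPWM("GACCTCCC", pwm,
        returnAll = TRUE)$normScore), d)
})

test_that("N-containing windows are skipped", {
    sc <- scanPWM("GACCNCCCGACCACCC", pwm, returnAll = TRUE)
    expect_false(any(sc$offset < 5L))  # every window over the N is dropped
    expect_true(any(sc$offset == 8L & sc$normScore == 1))
})

test_that("E-box detection matches the CANNTG pattern exactly", {
    expect_equal(findEbox("CAGCTG")$offset, 0L)
    expect_equal(nrow(findEbox("CAATAG")), 0L)
    expect_equal(findEbox("CACCTGCATGTG")$offset, c(0L, 6L))
    # pattern is its own reverse complement: revcomp leaves hit count equal
    expect_equal(nrow(findEbox(oracleRevcomp("CACCTGCATGTG"))), 2L)
})

test_that("core matches are reported on both strands, overlaps included", {
    expect_equal(findCore("ACCTCCA"), data.frame(offset = 1L, strand = "+"))
    expect_equal(findCore("AGGAGGA"), data.frame(offset = 1L, strand = "-"))
    cc <- findCore("CCTCCTCC")
    expect_equal(cc$offset[cc$strand == "+"], c(0L, 3L))
})

test_that("three-way classification is exhaustive and exclusive", {
    expect_equal(classifyPeak("TTTTGACCACCCTTTT", pwm)$class, "cGBM")
    expect_equal(classifyPeak("TTTTGACCTCCCTTTT", pwm)$class, "dGBM")
    expect_equal(classifyPeak(strrep("A", 30), pwm)$class, "neither")

    seqs <- DNAStringSet(c(p1 = "TTTTGACCACCCTTTT",
        p2 = "TTTTGACCTCCCTTTT", p3 = strrep("A", 16)))
    cl <- classifyPeakSet(seqs, pwm)
    expect_equal(unname(cl$fractions), rep(1 / 3, 3))
    expect_equal(sum(cl$fractions), 1)
    expect_equal(cl$table$class, c("cGBM", "dGBM", "neither"))
    expect_error(classifyPeakSet(DNAStringSet(), pwm), "empty")
})

test_that("canonical k-mer collapse picks the lexicographic minimum", {
    expect_equal(canonicalKmer("GACCACCC"), "GACCACCC")
    expect_equal(canonicalKmer("ACGTACGT"), "ACGTACGT")
    expect_equal(canonicalKmer("TTTTTTTT"), "AAAAAAAA")
    expect_error(canonicalKmer("ACGN"), "ambiguous")
    set.seed(5)
    for (i in 1:50) {
        w <- paste(sample(c("A", "C", "G", "T"), 8, TRUE), collapse = "")
        rc <- oracleRevcomp(w)
        expect_equal(canonicalKmer(w), min(w, rc))
    }
})

test_that("canonical k-mer space size follows the palindrome-corrected count", {
    expect_equal(enumerateCanonicalKmers(1), 2)
    expect_equal(enumerateCanonicalKmers(3), 32)
    expect_equal(enumerateCanonicalKmers(8), 32896)
    # brute force for k = 2: enumerate all 16 dimers and collapse
    dimers <- as.vector(outer(c("A", "C", "G", "T"),
        c("A", "C", "G", "T"), paste0))
    canon <- unique(vapply(dimers, function(w) min(w, oracleRevcomp(w)),
        character(1)))
    expect_equal(enumerateCanonicalKmers(2), length(canon))
    lst <- enumerateCanonicalKmers(2, list = TRUE)
    expect_setequal(lst$kmers, canon)
    expect_error(enumerateCanonicalKmers(0), "integer >= 1")
    expect_error(enumerateCanonicalKmers(13), "between 1 and 12")
})

test_that("k-mer census counts each window once, palindromes included", {
    cen <- countKmers("GACCACCCA", k = 8)
    expect_equal(sort(names(kmerCounts(cen))),
        sort(c(canonicalKmer("GACCACCC"), canonicalKmer("ACCACCCA"))))
    expect_true(all(kmerCounts(cen) == 1L))
    expect_equal(cen@totalPositions, 2)

    pal <- countKmers("ACGTACGT", k = 8)
    expect_equal(unname(kmerCounts(pal)["ACGTACGT"]), 1L)

    withN <- countKmers("GACCNCCCA", k = 8)
    expect_length(kmerCounts(withN), 0L)
    expect_equal(withN@totalPositions, 2)
})

test_that("k-mer census equals the dictionary oracle on random sequences", {
    set.seed(21)
    seqs <- vapply(1:50, function(i) paste(sample(c("A", "C", "G", "T"),
        200, TRUE), collapse = ""), character(1))
    cen <- countKmers(seqs, k = 8)
    expect_identical(kmerCounts(cen), bfCountKmers(seqs, 8))
    cen5 <- countKmers(seqs[1:10], k = 5)
    expect_identical(kmerCounts(cen5), bfCountKmers(seqs[1:10], 5))
})

test_that("ranking is competition order with lexicographic tie-break", {
    mk <- function(counts) new("KmerCensus", k = 8L,
        counts = counts[order(names(counts))], totalPositions = 1e6)
    cen <- mk(c(AAAACCCC = 5L, AAAAGGGG = 3L))
    expect_equal(kmerRank(cen, "AAAACCCC"), 1L)
    expect_equal(kmerRank(cen, "AAAAGGGG"), 2L)
    tie <- mk(c(AAAACCCC = 3L, AAAAGGGG = 3L))
    expect_equal(kmerRank(tie, "AAAACCCC"), 1L)
    expect_equal(kmerRank(tie, "AAAAGGGG"), 2L)
    # absent k-mer ranks after all present ones
    expect_equal(kmerRank(tie, "ACACACAC"), 3L)
    # reverse-complement queries rank identically
    expect_equal(kmerRank(tie, oracleRevcomp("AAAACCCC")), 1L)

    set.seed(13)
    seqs <- vapply(1:20, function(i) paste(sample(c("A", "C", "G", "T"),
        100, TRUE), collapse = ""), character(1))
    cen <- countKmers(seqs, k = 4)
    cnt <- kmerCounts(cen)
    ord <- names(cnt)[order(-cnt, names(cnt))]
    for (q in sample(ord, 20))
        expect_equal(kmerRank(cen, q), match(q, ord))
})

test_that("per-peak k-mer incidence counts presence on either strand", {
    seqs <- c(p1 = "TTGACCACCCTT", p2 = "TTGGGTGGTCTT",  # fwd / revcomp
        p3 = strrep("T", 12), p4 = strrep("A", 12))
    expect_equal(kmerPeakFraction(seqs, "GACCACCC"), 0.5)
    expect_equal(kmerPeakFraction(seqs[1:2], "GACCACCC"), 1.0)
    expect_error(kmerPeakFraction(character(0), "GACCACCC"), "empty")
})

test_that("motif statistics are invariant under strand reversal", {
    set.seed(31)
    seqs <- vapply(1:60, function(i) {
        s <- sample(c("A", "C", "G", "T"), 120, TRUE)
        if (i %% 3 == 0) s[40:47] <- strsplit("GACCACCC", "")[[1]]
        if (i %% 3 == 1) s[40:47] <- strsplit("GACCTCCC", "")[[1]]
        paste(s, collapse = "")
    }, character(1))
    rc <- vapply(seqs, oracleRevcomp, character(1))
    names(seqs) <- names(rc) <- sprintf("p%02d", 1:60)

    expect_identical(classifyPeakSet(seqs, pwm)$fractions,
        classifyPeakSet(rc, pwm)$fractions)
    expect_identical(kmerCounts(countKmers(seqs, 8)),
        kmerCounts(countKmers(rc, 8)))
    expect_equal(kmerPeakFraction(seqs, "GACCTCCC"),
        kmerPeakFraction(rc, "GACCTCCC"))
})
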