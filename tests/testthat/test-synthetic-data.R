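test_that("genome simulation respects GC content and the seed", {
    cfgAT <- simConfig(seed = 5, nChrom = 1L, chromLen = 5000, gc = 0)
    gen <- simulateGenome(cfgAT)
    expect_equal(GenomeInfoDb::seqlengths(gen$chroms)[["chr1"]], 5000L)
    expect_false(grepl("[GC]", as.character(gen$store[[1]])))

    cfg <- simConfig(seed = 6, nChrom = 1L, chromLen = 1e6, gc = 0.5)
    s <- as.character(simulateGenome(cfg)$store[[1]])
    gcObs <- mean(strsplit(s, "")[[1]] %in% c("G", "C"))
    expect_lt(abs(gcObs - 0.5), 3 * sqrt(0.25 / 1e6))

    s2 <- as.character(simulateGenome(cfg)$store[[1]])
    expect_identical(s, s2)
    expect_error(simConfig(gc = 1.2), "outside")
})

test_that("peak planting realises the requested overlap fraction", {
    cfg1 <- simConfig(seed = 9, nChrom = 1L, chromLen = 2e6,
        nPeaksA = 100L, nPeaksB = 100L, overlapFrac = 1)
    gen <- simulateGenome(cfg1)
    pk <- simulatePeakSets(cfg1, gen$chroms)
    expect_equal(intersectPeaks(pk$a, pk$b)$fracA, 1.0)
    expect_true(all(pk$truth$planted_overlap))

    cfg0 <- simConfig(seed = 9, nChrom = 1L, chromLen = 2e6,
        nPeaksA = 100L, nPeaksB = 100L, overlapFrac = 0)
    pk0 <- simulatePeakSets(cfg0, gen$chroms)
    expect_equal(intersectPeaks(pk0$a, pk0$b)$fracA, 0)

    # a-peaks never overlap one another (each owns its footprint)
    expect_equal(sum(countOverlaps(pk$a, pk$a) > 1L), 0L)
    expect_error(simulatePeakSets(
        simConfig(nPeaksA = 10000L, nPeaksB = 10000L, nChrom = 1L,
            chromLen = 1e5), gen$chroms), "infeasible|longer")
})

test_that("motif embedding reproduces planned classes, gaps and strands", {
    cfg <- simConfig(seed = 15, nChrom = 1L, chromLen = 3e5,
        nPeaksA = 30L, nPeaksB = 10L, overlapFrac = 0)
    gen <- simulateGenome(cfg)
    pk <- simulatePeakSets(cfg, gen$chroms)
    plan <- data.frame(peak = names(pk$a),
        class = rep(c("cGBM", "dGBM", "neither"), each = 10L),
        ebox = rep(c(TRUE, FALSE, TRUE), 10L),
        gap = NA_integer_)
    plan$gap[plan$class == "dGBM" & plan$ebox] <- 2L
    plan$gap[plan$class == "cGBM" & plan$ebox] <- -22L
    emb <- embedMotifs(gen$store, pk$a, plan, seed = 44L)
    seqs <- peakSequences(pk$a, emb$store)
    cl <- classifyPeakSet(seqs)
    expect_identical(unname(cl$table$class[match(plan$peak, cl$table$peak)]),
        plan$class)

    led <- emb$ledger
    # every planted GBM is recoverable at its recorded offset and strand
    gbm <- led[led$kind %in% c("cgbm", "dgbm"), ]
    for (r in seq_len(nrow(gbm))) {
        s <- as.character(seqs[[gbm$peak[r]]])
        motif <- if (gbm$kind[r] == "cgbm") "GACCACCC" else "GACCTCCC"
        want <- if (gbm$strand[r] == "-") oracleRevcomp(motif) else motif
        expect_equal(substr(s, gbm$offset[r] + 1, gbm$offset[r] + 8), want)
    }
    # E-box gaps round-trip through composite-site detection
    eb <- led[led$kind == "ebox" & !is.na(led$gap), ]
    for (r in seq_len(nrow(eb))) {
        s <- as.character(seqs[[eb$peak[r]]])
        expect_equal(substr(s, eb$offset[r] + 1, eb$offset[r] + 2), "CA")
        expect_equal(substr(s, eb$offset[r] + 5, eb$offset[r] + 6), "TG")
    }
    # every peak planted with a +2 gap yields a recovered +2 pair (chance
    # background E-boxes may add further pairs)
    plus2 <- unique(eb$peak[eb$gap == 2L])
    sites <- compositeSites(seqs[plus2], threshold = 0.7)
    expect_setequal(unique(sites$pairs$peak[sites$pairs$gap == 2L]), plus2)
})

test_that("the planted PP1-style geometry round-trips exactly", {
    # E-box, 22 bp gap, divergent GBM, 2 bp gap, E-box
    cfg <- simConfig(seed = 16, nChrom = 1L, chromLen = 1e5, nPeaksA = 1L,
        nPeaksB = 1L, overlapFrac = 0)
    gen <- simulateGenome(cfg)
    pk <- simulatePeakSets(cfg, gen$chroms)
    plan1 <- data.frame(peak = names(pk$a)[1], class = "dGBM", ebox = TRUE,
        gap = -22L)
    emb1 <- embedMotifs(gen$store, pk$a, plan1, seed = 3L)
    led <- emb1$ledger
    gOff <- led$offset[led$kind == "dgbm"]
    eOff <- led$offset[led$kind == "ebox"]
    expect_equal(gOff - (eOff + 6L), 22L)

    seqChar <- as.character(peakSequences(pk$a, emb1$store)[[1]])
    s <- strsplit(seqChar, "")[[1]]
    s[(gOff + 8L + 2L) + 1:6] <- strsplit("CACGTG", "")[[1]]  # second E-box
    sites <- compositeSites(setNames(paste(s, collapse = ""), "pp1"),
        threshold = 0.7, window = 100L)
    anchored <- sites$pairs[sites$pairs$gbm_offset == gOff, ]
    expect_true(all(c(-22L, 2L) %in% anchored$gap))
})

test_that("gene annotation is non-overlapping, seeded, and TSS-consistent", {
    cfg <- simConfig(seed = 25, nChrom = 2L, chromLen = 1e6,
        nGenes = 300L)
    chroms <- chromTable(c("chr1", "chr2"), c(1e6, 1e6))
    genes <- simulateGeneAnnotation(cfg, chroms)
    expect_length(genes, 300L)
    expect_equal(sum(countOverlaps(genes, genes) > 1L), 0L)
    tss <- mcols(genes)$tss
    expect_true(all(tss >= start(genes) - 1L & tss <= end(genes)))
    genes2 <- simulateGeneAnnotation(cfg, chroms)
    expect_identical(as.data.frame(genes), as.data.frame(genes2))

    one <- simulateGeneAnnotation(simConfig(nGenes = 1L, nDE = 1L,
        nChrom = 1L, chromLen = 1e5, seed = 2), chromTable("chr1", 1e5))
    expect_length(one, 1L)

    # mean inter-TSS spacing tracks genome length / gene count
    gaps <- diff(sort(tss[as.character(seqnames(genes)) == "chr1"]))
    expect_lt(abs(mean(gaps) - 1e6 / 150) / (1e6 / 150), 0.25)
})

test_that("DE tables realise shared and concordant fractions by design", {
    chroms <- chromTable("chr1", 1e6)
    cfgFull <- simConfig(seed = 33, nChrom = 1L, chromLen = 1e6,
        nGenes = 500L, nDE = 100L, sharedFrac = 1, concordantFrac = 1)
    genes <- simulateGeneAnnotation(cfgFull, chroms)
    de <- simulateDETables(cfgFull, genes)
    fa <- deFilter(de$a); fb <- deFilter(de$b)
    expect_setequal(fa$gene_id, fb$gene_id)
    sa <- setNames(fa$sign, fa$gene_id)
    expect_true(all(sa[fb$gene_id] == fb$sign))

    cfg0 <- simConfig(seed = 33, nChrom = 1L, chromLen = 1e6,
        nGenes = 500L, nDE = 100L, sharedFrac = 0)
    de0 <- simulateDETables(cfg0, genes)
    expect_length(intersect(deFilter(de0$a)$gene_id,
        deFilter(de0$b)$gene_id), 0L)

    # filtering recovers exactly the planted sets (generator contract)
    cfgHalf <- simConfig(seed = 34, nGenes = 500L, nDE = 100L,
        sharedFrac = 0.5, concordantFrac = 0.8)
    deH <- simulateDETables(cfgHalf, genes)
    expect_setequal(deFilter(deH$a)$gene_id, deH$truth$deA)
    expect_setequal(deFilter(deH$b)$gene_id, deH$truth$deB)
    expect_length(intersect(deH$truth$deA, deH$truth$deB), 50L)
    conc <- directionConcordance(deH$a, deH$b, deH$truth$shared)
    expect_equal(unname(conc["discordant"]), 0.2)
})

test_that("reporter generation hits the planted additive expectations", {
    noiseless <- simConfig(seed = 41, effectA = 2, effectB = 2,
        interaction = 1, reporterCV = 0, nRep = 3L)
    tab <- simulateReporterData(noiseless, constructs = c(c1 = 1))
    norm <- normalizeReporter(tab)
    ab <- norm$relative[norm$condition == "AB"]
    expect_equal(ab, rep(2 + 2 - 1, 3))

    doubled <- simConfig(seed = 41, effectA = 2, effectB = 2,
        interaction = 2, reporterCV = 0, nRep = 3L)
    tab2 <- normalizeReporter(simulateReporterData(doubled,
        constructs = c(c1 = 2)))
    expect_equal(tab2$relative[tab2$condition == "AB"], rep(6, 3))

    cfg <- simConfig(seed = 42, reporterCV = 0.1)
    expect_identical(simulateReporterData(cfg), simulateReporterData(cfg))
})

test_that("a simulated study is written completely and deterministically", {
    cfg <- simConfig(seed = 55, nChrom = 1L, chromLen = 4e5, nPeaksA = 40L,
        nPeaksB = 40L, nGenes = 150L, nDE = 40L)
    d1 <- file.path(tempdir(), "study1")
    sim <- simulateStudy(cfg, d1)
    for (p in sim$paths)
        expect_true(file.exists(p))
    truth <- jsonlite::read_json(sim$paths$truth)
    expect_equal(truth$seed, 55L)
    expect_length(truth$planted_overlap, round(0.6 * 40))

    # the planted class plan is recovered from the written files
    chroms <- readChromSizes(sim$paths$sizes)
    store <- readGenome(sim$paths$genome, chroms)
    peaks <- readPeaks(sim$paths$peaksA, chroms)
    cl <- classifyPeakSet(peakSequences(peaks, store))
    expect_identical(
        unname(cl$table$class[match(sim$plan$peak, cl$table$peak)]),
        sim$plan$class)

    d2 <- file.path(tempdir(), "study2")
    simulateStudy(cfg, d2)
    for (f in list.files(d1))
        expect_identical(readLines(file.path(d1, f)),
            readLines(file.path(d2, f)), label = f)
})
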