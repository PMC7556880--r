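# End-to-end analysis over a simulated (or equivalently formatted) study
# directory; every stochastic stage is seeded so two runs are byte-identical.

.enrichToList <- function(x) {
    list(observed = x@observed, null_mean = x@nullMean, null_sd = x@nullSd,
        fold = x@fold, z = x@z, p_empirical = x@pEmpirical,
        p_normal = x@pNormal, n_perm = x@nPerm, seed = x@seed)
}

.synergyToList <- function(x) {
    list(construct = x@construct,
        condition_means = as.list(x@conditionMeans),
        expected_additive = x@expectedAdditive, excess = x@excess,
        statistic = x@statistic, df = x@df, p_synergy = x@pSynergy,
        method = x@method,
        comparisons = x@comparisons)
}

#' Run the full co-occupancy / motif / integration pipeline
#'
#' Consumes a study directory as written by [simulateStudy()] (genome FASTA,
#' chromosome sizes, per-replicate BED files for factors A and B, gene
#' annotation, two DE tables, marker sets, reporter table, PWM) and executes
#' the complete analysis: replicate merging, overlap and permutation
#' enrichment, motif classification of overlapping versus A-only peaks, the
#' canonical 8-mer census with consensus-motif incidence and rank, the
#' GBM/E-box spacing-orientation grid, DE filtering with hypergeometric
#' overlap and direction concordance, DE counts by peak category, marker-set
#' proximity enrichment, and reporter synergy tests.
#'
#' @param dir study directory.
#' @param outdir output directory for `summary.json`, `classes.tsv`,
#'   `kmers_overlap.tsv`, `kmers_a_only.tsv`, `spacing.tsv`.
#' @param seed seed driving all permutation stages.
#' @param nPerm permutations for the enrichment tests.
#' @param spacingPerm null draws for the per-configuration spacing test
#'   (default 20000: Benjamini-Hochberg across the ~400 grid cells needs a
#'   Monte-Carlo floor well below 0.05/ncells).
#' @param threshold PWM fraction-of-maximum threshold for classification.
#' @param spacingThreshold laxer PWM threshold used when pairing GBMs with
#'   E-boxes (default 0.7, so divergent sites anchor pairs too).
#' @param window spacing window in bp.
#' @param minSupport replicate support required by [mergeReplicates()].
#' @return invisibly, the summary list (also written as JSON).
#' @export
runPipeline <- function(dir, outdir, seed = 1L, nPerm = 1000L,
        spacingPerm = 20000L, threshold = 0.8, spacingThreshold = 0.7,
        window = 100L, minSupport = 2L) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    chroms <- readChromSizes(file.path(dir, "chrom_sizes.tsv"))
    store <- readGenome(file.path(dir, "genome.fa"), chroms)
    pwm <- readPWM(file.path(dir, "gbm.pwm"))
    seeds <- subSeeds(seed, 6L)

    repA <- lapply(c("peaks_a_rep1.bed", "peaks_a_rep2.bed"),
        function(f) readPeaks(file.path(dir, f), chroms))
    repB <- lapply(c("peaks_b_rep1.bed", "peaks_b_rep2.bed"),
        function(f) readPeaks(file.path(dir, f), chroms))
    a <- mergeReplicates(repA, minSupport = minSupport)
    b <- mergeReplicates(repB, minSupport = minSupport)
    names(a) <- sprintf("a_%04d", seq_along(a))
    names(b) <- sprintf("b_%04d", seq_along(b))

    ov <- intersectPeaks(a, b)
    enrich <- permutationOverlapTest(a, b, chroms, nPerm = nPerm,
        seed = seeds[1L])

    seqOv <- peakSequences(ov$overlap, store)
    seqAOnly <- peakSequences(a[!ov$hits], store)
    clsOv <- classifyPeakSet(seqOv, pwm, threshold = threshold)
    clsAOnly <- classifyPeakSet(seqAOnly, pwm, threshold = threshold)

    cenOv <- countKmers(seqOv, k = 8L)
    cenAOnly <- countKmers(seqAOnly, k = 8L)
    consensus <- .MOTIF_CGBM
    kmerStats <- list(
        consensus = consensus,
        rank_overlap = kmerRank(cenOv, consensus),
        rank_a_only = kmerRank(cenAOnly, consensus),
        peak_fraction_overlap = kmerPeakFraction(seqOv, consensus),
        peak_fraction_a_only = kmerPeakFraction(seqAOnly, consensus),
        canonical_8mer_space = enumerateCanonicalKmers(8L))

    sites <- compositeSites(seqOv, pwm, threshold = spacingThreshold,
        window = window)
    grid <- spacingGrid(sites, window = window)
    spacingTab <- configEnrichmentTest(grid, nPerm = spacingPerm,
        seed = seeds[2L])
    maxCfg <- if (grid@total > 0L) maxConfigFraction(grid) else
        list(orientation = NA, gap = NA, fraction = NA)

    deA <- readExprTable(file.path(dir, "de_a.tsv"))
    deB <- readExprTable(file.path(dir, "de_b.tsv"))
    fA <- deFilter(deA)
    fB <- deFilter(deB)
    universe <- intersect(deA$gene_id, deB$gene_id)
    hyper <- hypergeometricOverlap(fA$gene_id, fB$gene_id, universe)
    sharedDE <- intersect(fA$gene_id, fB$gene_id)
    conc <- if (length(sharedDE))
        directionConcordance(deA, deB, sharedDE) else
        c(up_up = NA, down_down = NA, discordant = NA)

    genes <- readGeneAnnotation(file.path(dir, "genes.tsv"), chroms)
    nearA <- nearestGenes(a, genes)
    peakGenes <- data.frame(
        peak = rep(nearA$peak, 2L),
        gene_id = c(nearA$upstream_gene, nearA$downstream_gene),
        stringsAsFactors = FALSE)
    peakGenes <- peakGenes[!is.na(peakGenes$gene_id), ]
    category <- stats::setNames(ifelse(ov$hits, "overlap", "a_only"),
        names(a))
    deByCat <- deCountsByPeakClass(fA$gene_id, peakGenes, category)
    classByPeak <- stats::setNames(
        c(clsOv$table$class, clsAOnly$table$class),
        c(clsOv$table$peak, clsAOnly$table$peak))
    deByClass <- deCountsByPeakClass(fA$gene_id, peakGenes, classByPeak)

    markers <- utils::read.table(file.path(dir, "markers.tsv"), sep = "\t",
        header = TRUE, stringsAsFactors = FALSE)
    nearOv <- nearestGenes(ov$overlap, genes)
    proximal <- sort(unique(stats::na.omit(c(nearOv$upstream_gene,
        nearOv$downstream_gene))))
    markerEnrich <- lapply(split(markers$gene_id, markers$cluster),
        function(set) genesetProximityEnrichment(
            intersect(set, mcols(genes)$gene_id), proximal,
            mcols(genes)$gene_id, nPerm = nPerm, seed = seeds[3L]))

    reporter <- readReporterTable(file.path(dir, "reporter.tsv"))
    synergy <- synergyTest(normalizeReporter(reporter), seed = seeds[4L])
    if (is(synergy, "SynergyStat"))
        synergy <- stats::setNames(list(synergy), synergy@construct)

    summary <- list(
        seed = seed,
        peaks = list(n_a = length(a), n_b = length(b),
            n_overlap = length(ov$overlap), frac_a = ov$fracA),
        overlap_enrichment = .enrichToList(enrich),
        class_fractions = list(overlap = as.list(clsOv$fractions),
            a_only = as.list(clsAOnly$fractions)),
        kmers = kmerStats,
        spacing = list(window = window, total_pairs = grid@total,
            n_peaks_with_pair = grid@nPeaksWithPair,
            max_config = maxCfg,
            n_cells_flagged = sum(spacingTab$p_adj < 0.05)),
        expression = list(hypergeometric = hyper,
            concordance = as.list(conc),
            de_by_category = as.list(deByCat$counts),
            de_by_motif_class = as.list(deByClass$counts)),
        marker_enrichment = lapply(markerEnrich, .enrichToList),
        synergy = lapply(synergy, .synergyToList))

    utils::write.table(rbind(clsOv$table, clsAOnly$table),
        file.path(outdir, "classes.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    writeKmerCensus <- function(cen, path) {
        cnt <- kmerCounts(cen)
        ord <- order(-cnt, names(cnt), method = "radix")
        utils::write.table(data.frame(kmer = names(cnt)[ord],
            count = unname(cnt[ord]), rank = seq_along(ord)),
            path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    writeKmerCensus(cenOv, file.path(outdir, "kmers_overlap.tsv"))
    writeKmerCensus(cenAOnly, file.path(outdir, "kmers_a_only.tsv"))
    utils::write.table(spacingTab, file.path(outdir, "spacing.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(summary)
}
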