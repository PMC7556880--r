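#' @importFrom stats rnorm runif rexp
NULL

# fixed sub-seed slots so each generator is deterministic standalone
.SEED_GENOME <- 1L; .SEED_PEAKS <- 2L; .SEED_EMBED <- 3L
.SEED_GENES <- 4L; .SEED_DE <- 5L; .SEED_REPORTER <- 6L
.SEED_MARKERS <- 7L; .SEED_REPL <- 8L

#' Build a simulation configuration
#'
#' Defaults encode the study conditions the pipeline emulates; see
#' [SimConfig-class] and the methods vignette for the rationale.
#'
#' @param seed master seed; every generator derives its own sub-seed from it.
#' @param nChrom,chromLen,gc genome: chromosome count, length (bp), GC
#'   fraction (0.42, a mammalian genome-wide value).
#' @param nPeaksA,nPeaksB,overlapFrac,peakLenMean,peakLenSd peak plan; 60% of
#'   A peaks are planted on top of a B peak.
#' @param classProbsOverlap,classProbsAOnly motif-class mix for overlapping
#'   (9% cGBM / 85% dGBM / 6% neither) and A-only (16% cGBM) peaks.
#' @param eboxProb,eboxGap,eboxWindow E-box co-planting: probability, fixed
#'   signed gap (NA draws uniformly in \code{[-eboxWindow, eboxWindow]}), and
#'   window.
#' @param nGenes,geneLenMin,geneLenMax gene annotation plan.
#' @param nDE,sharedFrac,concordantFrac,downFrac,log2fcMag differential
#'   expression plan: per-table DE count, fraction shared between tables,
#'   fraction of shared genes with matching sign, fraction of concordant
#'   genes down in both, and the mean |log2FC| margin above the 1.5-fold
#'   threshold.
#' @param reporterBaseline,effectA,effectB,interaction,reporterCV,nRep
#'   reporter plan; the combined-condition mean is
#'   \code{(effectA + effectB - 1) * interaction} on the control-relative
#'   scale, with multiplicative log-normal noise of the given CV.
#' @return a validated [SimConfig-class].
#' @export
simConfig <- function(seed = 1L, nChrom = 2L, chromLen = 2.5e6, gc = 0.42,
        nPeaksA = 500L, nPeaksB = 500L, overlapFrac = 0.6,
        peakLenMean = 300, peakLenSd = 50,
        classProbsOverlap = c(cGBM = 0.09, dGBM = 0.85, neither = 0.06),
        classProbsAOnly = c(cGBM = 0.16, dGBM = 0.42, neither = 0.42),
        eboxProb = 0.7, eboxGap = NA_real_, eboxWindow = 100L,
        nGenes = 1000L, geneLenMin = 500L, geneLenMax = 2000L,
        nDE = 200L, sharedFrac = 0.5, concordantFrac = 1.0, downFrac = 0.58,
        log2fcMag = 1.0,
        reporterBaseline = 1, effectA = 2, effectB = 2, interaction = 2,
        reporterCV = 0.1, nRep = 6L) {
    new("SimConfig", seed = as.integer(seed), nChrom = as.integer(nChrom),
        chromLen = as.numeric(chromLen), gc = gc,
        nPeaksA = as.integer(nPeaksA), nPeaksB = as.integer(nPeaksB),
        overlapFrac = overlapFrac, peakLenMean = peakLenMean,
        peakLenSd = peakLenSd, classProbsOverlap = classProbsOverlap,
        classProbsAOnly = classProbsAOnly, eboxProb = eboxProb,
        eboxGap = as.numeric(eboxGap), eboxWindow = as.integer(eboxWindow),
        nGenes = as.integer(nGenes), geneLenMin = as.integer(geneLenMin),
        geneLenMax = as.integer(geneLenMax), nDE = as.integer(nDE),
        sharedFrac = sharedFrac, concordantFrac = concordantFrac,
        downFrac = downFrac, log2fcMag = log2fcMag,
        reporterBaseline = reporterBaseline, effectA = effectA,
        effectB = effectB, interaction = interaction,
        reporterCV = reporterCV, nRep = as.integer(nRep))
}

#' Simulate a genome
#'
#' I.i.d. bases with \code{P(G) = P(C) = gc/2}; byte-identical under the same
#' seed.
#'
#' @param cfg a [SimConfig-class].
#' @return list with `chroms` (Seqinfo) and `store` (named DNAStringSet).
#' @export
simulateGenome <- function(cfg) {
    set.seed(subSeeds(cfg@seed, .SEED_GENOME)[.SEED_GENOME])
    p <- c((1 - cfg@gc) / 2, cfg@gc / 2, cfg@gc / 2, (1 - cfg@gc) / 2)
    nms <- paste0("chr", seq_len(cfg@nChrom))
    seqs <- vapply(nms, function(nm)
        paste(sample(BASES, cfg@chromLen, replace = TRUE, prob = p),
            collapse = ""), character(1))
    store <- DNAStringSet(seqs)
    names(store) <- nms
    list(chroms = chromTable(nms, rep(cfg@chromLen, cfg@nChrom)),
        store = store)
}

# draw peak lengths: truncated normal, minimum 50 bp
.peakLens <- function(n, mean, sd) {
    pmax(50L, as.integer(round(stats::rnorm(n, mean, sd))))
}

# uniform (chrom, start) placement for peaks of the given lengths
.placeUniform <- function(lens, chroms) {
    L <- seqlengths(chroms)
    chr <- sample(seqlevels(chroms), length(lens), replace = TRUE,
        prob = L / sum(L))
    maxStart <- L[chr] - lens  # bed-start upper bound
    if (any(maxStart < 0))
        stop("peak longer than chromosome")
    start <- floor(stats::runif(length(lens)) * (maxStart + 1))
    GRanges(chr, IRanges(start + 1, width = lens), seqinfo = chroms)
}

#' Simulate two peak sets with a planted overlap fraction
#'
#' B peaks are placed uniformly; \code{round(overlapFrac * nPeaksA)} A peaks
#' are planted to overlap a random B peak by at least 1 bp and the remaining A
#' peaks are placed uniformly avoiding B (and all other A peaks, so each A
#' peak carries its own sequence footprint).
#'
#' @param cfg a [SimConfig-class].
#' @param chroms `Seqinfo` from [simulateGenome()].
#' @return list with `a`, `b` (named `GRanges`) and `truth` (data.frame:
#'   peak, planted_overlap).
#' @export
simulatePeakSets <- function(cfg, chroms) {
    set.seed(subSeeds(cfg@seed, .SEED_PEAKS)[.SEED_PEAKS])
    totalBp <- (cfg@nPeaksA + cfg@nPeaksB) * cfg@peakLenMean
    if (totalBp > sum(seqlengths(chroms)))
        stop("infeasible peak density: total peak bp exceeds the genome")
    b <- .placeUniform(.peakLens(cfg@nPeaksB, cfg@peakLenMean, cfg@peakLenSd),
        chroms)
    names(b) <- sprintf("b_%04d", seq_along(b))

    nOv <- round(cfg@overlapFrac * cfg@nPeaksA)
    lensA <- .peakLens(cfg@nPeaksA, cfg@peakLenMean, cfg@peakLenSd)
    placed <- GRanges(seqinfo = chroms)
    aList <- vector("list", cfg@nPeaksA)
    for (i in seq_len(cfg@nPeaksA)) {
        len <- lensA[i]
        for (try in seq_len(1000L)) {
            if (i <= nOv) {
                j <- sample.int(length(b), 1L)
                chr <- as.character(seqnames(b))[j]
                L <- seqlengths(chroms)[[chr]]
                lo <- max(0L, start(b)[j] - 1L - len + 1L)
                hi <- min(L - len, end(b)[j] - 1L)
                s <- lo + floor(stats::runif(1) * (hi - lo + 1))
                g <- GRanges(chr, IRanges(s + 1, width = len),
                    seqinfo = chroms)
            } else {
                g <- .placeUniform(len, chroms)
                if (sum(countOverlaps(g, b)) > 0L)
                    next
            }
            if (sum(countOverlaps(g, placed)) == 0L) {
                aList[[i]] <- g
                placed <- c(placed, g)
                break
            }
        }
        if (is.null(aList[[i]]))
            stop("could not place A peak ", i,
                " after 1000 attempts (genome too dense)")
    }
    a <- unlist(GRangesList(aList))
    names(a) <- sprintf("a_%04d", seq_along(a))
    a <- BiocGenerics::sort(a, ignore.strand = TRUE)
    truth <- data.frame(peak = names(a),
        planted_overlap = as.integer(sub("a_", "", names(a))) <= nOv,
        stringsAsFactors = FALSE)
    list(a = a, b = b, truth = truth)
}

#' Plan motif content for a set of peaks
#'
#' Samples a motif class (cGBM / dGBM / neither) for each peak from the
#' class-probability vector matching its planted overlap status, decides
#' E-box co-planting, and draws the signed GBM/E-box gap (fixed `eboxGap` or
#' uniform within `eboxWindow`).
#'
#' @param cfg a [SimConfig-class].
#' @param peaks named A-peak `GRanges`.
#' @param overlapping logical vector over `peaks`: planted-overlap status.
#' @param seed RNG seed (default derived from `cfg`).
#' @return data.frame: peak, class, ebox, gap.
#' @export
planPeakMotifs <- function(cfg, peaks, overlapping,
        seed = subSeeds(cfg@seed, .SEED_EMBED)[.SEED_EMBED]) {
    set.seed(as.integer(seed))
    classes <- c("cGBM", "dGBM", "neither")
    cls <- character(length(peaks))
    overlapping <- as.logical(overlapping)
    cls[overlapping] <- sample(classes, sum(overlapping), replace = TRUE,
        prob = cfg@classProbsOverlap[classes])
    cls[!overlapping] <- sample(classes, sum(!overlapping), replace = TRUE,
        prob = cfg@classProbsAOnly[classes])
    ebox <- stats::runif(length(peaks)) < cfg@eboxProb
    gap <- rep(NA_integer_, length(peaks))
    need <- ebox & cls != "neither"
    if (is.na(cfg@eboxGap)) {
        gap[need] <- sample(seq(-cfg@eboxWindow, cfg@eboxWindow),
            sum(need), replace = TRUE)
    } else {
        gap[need] <- as.integer(cfg@eboxGap)
    }
    data.frame(peak = names(peaks), class = cls, ebox = ebox, gap = gap,
        stringsAsFactors = FALSE)
}

.MOTIF_CGBM <- "GACCACCC"
.MOTIF_DGBM <- "GACCTCCC"

# mutate chance PWM hits (and optionally core matches) out of a sequence
.scrubSeq <- function(seq, pwm, threshold, core, forbidCore, maxIter = 200L) {
    L <- nrow(pwm@probs)
    for (iter in seq_len(maxIter)) {
        bad <- scanPWM(seq, pwm, threshold = threshold)
        windows <- if (nrow(bad)) cbind(bad$offset, bad$offset + L) else
            matrix(numeric(0), ncol = 2)
        if (forbidCore) {
            cr <- findCore(seq, core = core)
            if (nrow(cr))
                windows <- rbind(windows,
                    cbind(cr$offset, cr$offset + nchar(core)))
        }
        if (!nrow(windows))
            return(seq)
        for (w in seq_len(nrow(windows))) {
            pos <- windows[w, 1L] + sample.int(windows[w, 2L] -
                windows[w, 1L], 1L)  # 1-based position inside window
            old <- substr(seq, pos, pos)
            substr(seq, pos, pos) <- sample(setdiff(BASES, old), 1L)
        }
    }
    stop("could not scrub motif matches from a background sequence")
}

# draw one of the 16 CANNTG realisations
.randomEbox <- function() {
    paste0("CA", paste(sample(BASES, 2L, replace = TRUE), collapse = ""),
        "TG")
}

#' Embed planned motifs into peak sequences
#'
#' For each planned peak the background footprint (peak plus `margin` bp each
#' side) is first scrubbed of chance PWM hits — and, for peaks planted as
#' class \code{neither}, of core matches — by point mutation; the planned
#' motifs are then written at random non-colliding offsets (the GBM on a
#' random strand, reverse-complemented on minus; the E-box as one of the 16
#' CANNTG realisations at the planned signed gap).  The resulting class is
#' verified with [classifyPeak()] and the placement retried up to
#' `maxAttempts` times; failure to place is an error naming the peak.
#'
#' @param store named `DNAStringSet` chromosome sequences.
#' @param peaks named A-peak `GRanges` (mutually non-overlapping).
#' @param plan data.frame from [planPeakMotifs()].
#' @param pwm,threshold,core classification parameters used for scrubbing and
#'   verification.
#' @param margin extra scrubbed bp on each side of a peak (default 50), so
#'   that replicate-jittered or merged spans stay clean.
#' @param maxAttempts placement attempts per peak (default 100).
#' @param seed RNG seed.
#' @return list with `store` (modified sequences) and `ledger` (data.frame:
#'   peak, kind, offset, strand, gap) recording every planted instance.
#' @export
embedMotifs <- function(store, peaks, plan, pwm = gbmMatrix(),
        threshold = 0.8, core = "CCTCC", margin = 50L, maxAttempts = 100L,
        seed = subSeeds(1L, .SEED_EMBED)[.SEED_EMBED]) {
    set.seed(as.integer(seed))
    chromChars <- stats::setNames(as.character(store), names(store))
    ledger <- vector("list", nrow(plan))
    peakIdx <- match(plan$peak, names(peaks))
    if (anyNA(peakIdx))
        stop("plan refers to unknown peak(s)")
    if (!all(plan$class %in% c("cGBM", "dGBM", "neither")))
        stop("plan classes must be cGBM, dGBM or neither")
    Lg <- nchar(.MOTIF_CGBM)
    for (r in seq_len(nrow(plan))) {
        i <- peakIdx[r]
        chr <- as.character(seqnames(peaks))[i]
        chromLen <- nchar(chromChars[[chr]])
        s0 <- max(1L, start(peaks)[i] - margin)        # 1-based, margin incl.
        e0 <- min(chromLen, end(peaks)[i] + margin)
        pOff <- start(peaks)[i] - s0                   # peak offset in window
        pLen <- width(peaks)[i]
        cls <- plan$class[r]
        wantEbox <- plan$ebox[r]
        gap <- plan$gap[r]
        if (pLen < Lg + 6L + ifelse(is.na(gap), 0L, abs(gap)))
            stop("peak ", plan$peak[r],
                " too short for its planned insertions")
        base <- substr(chromChars[[chr]], s0, e0)
        placedRows <- NULL
        done <- FALSE
        for (attempt in seq_len(maxAttempts)) {
            seq <- .scrubSeq(base, pwm, threshold, core,
                forbidCore = (cls == "neither"))
            rows <- NULL
            ok <- TRUE
            if (cls %in% c("cGBM", "dGBM")) {
                motif <- if (cls == "cGBM") .MOTIF_CGBM else .MOTIF_DGBM
                strandG <- sample(c("+", "-"), 1L)
                ins <- if (strandG == "-") revcomp(motif) else motif
                gOff <- NA_integer_
                eOff <- NA_integer_
                if (wantEbox && !is.na(gap)) {
                    # choose a GBM offset leaving room for the E-box
                    loG <- if (gap >= 0) 0L else abs(gap) + 6L
                    hiG <- if (gap >= 0) pLen - Lg - gap - 6L else pLen - Lg
                    if (hiG < loG) { ok <- FALSE }
                    else {
                        gOff <- loG + floor(stats::runif(1) * (hiG - loG + 1))
                        eOff <- if (gap >= 0) gOff + Lg + gap else
                            gOff + gap - 6L
                    }
                } else {
                    gOff <- floor(stats::runif(1) * (pLen - Lg + 1))
                }
                if (ok) {
                    substr(seq, pOff + gOff + 1L,
                        pOff + gOff + Lg) <- ins
                    rows <- data.frame(peak = plan$peak[r],
                        kind = tolower(cls), offset = gOff,
                        strand = strandG, gap = NA_integer_,
                        stringsAsFactors = FALSE)
                    if (wantEbox && !is.na(eOff)) {
                        eb <- .randomEbox()
                        substr(seq, pOff + eOff + 1L,
                            pOff + eOff + 6L) <- eb
                        rows <- rbind(rows, data.frame(peak = plan$peak[r],
                            kind = "ebox", offset = eOff, strand = ".",
                            gap = gap, stringsAsFactors = FALSE))
                    }
                }
            } else if (wantEbox) {
                eOff <- floor(stats::runif(1) * (pLen - 6L + 1))
                eb <- .randomEbox()
                substr(seq, pOff + eOff + 1L, pOff + eOff + 6L) <- eb
                rows <- data.frame(peak = plan$peak[r], kind = "ebox",
                    offset = eOff, strand = ".", gap = NA_integer_,
                    stringsAsFactors = FALSE)
            }
            if (!ok)
                next
            peakSeq <- substr(seq, pOff + 1L, pOff + pLen)
            if (classifyPeak(peakSeq, pwm, threshold = threshold,
                    core = core)$class == cls || cls == "none") {
                chromChars[[chr]] <- paste0(
                    substr(chromChars[[chr]], 1L, s0 - 1L), seq,
                    substr(chromChars[[chr]], e0 + 1L, chromLen))
                placedRows <- rows
                done <- TRUE
                break
            }
        }
        if (!done)
            stop("could not realise planned motif content for peak ",
                plan$peak[r], " in ", maxAttempts, " attempts")
        ledger[[r]] <- placedRows
    }
    ledger <- do.call(rbind, ledger[!vapply(ledger, is.null, TRUE)])
    if (is.null(ledger))
        ledger <- data.frame(peak = character(0), kind = character(0),
            offset = integer(0), strand = character(0), gap = integer(0),
            stringsAsFactors = FALSE)
    newStore <- DNAStringSet(chromChars)
    names(newStore) <- names(store)
    list(store = newStore, ledger = ledger)
}

#' Simulate a gene annotation
#'
#' Non-overlapping gene bodies with uniform placement and random strands; the
#' TSS is the 5' end of the body (body start on plus, body end on minus).
#'
#' @param cfg a [SimConfig-class].
#' @param chroms `Seqinfo`.
#' @return gene `GRanges` with mcols `gene_id` and `tss` (0-based).
#' @export
simulateGeneAnnotation <- function(cfg, chroms) {
    set.seed(subSeeds(cfg@seed, .SEED_GENES)[.SEED_GENES])
    L <- as.numeric(seqlengths(chroms))
    names(L) <- seqlevels(chroms)
    nPer <- round(cfg@nGenes * L / sum(L))
    # fix rounding drift on the last chromosome
    nPer[length(nPer)] <- cfg@nGenes - sum(nPer[-length(nPer)])
    out <- vector("list", length(L))
    gi <- 0L
    for (ci in seq_along(L)) {
        n <- nPer[ci]
        if (n < 1L) next
        lens <- sample(seq(cfg@geneLenMin, cfg@geneLenMax), n, replace = TRUE)
        free <- L[ci] - sum(lens)
        if (free < n)
            stop("infeasible gene count for chromosome ", names(L)[ci])
        gaps <- diff(c(0L, sort(sample.int(free, n)), free))
        starts <- cumsum(gaps[seq_len(n)] + c(0L, lens[-n]))  # bed starts
        std <- sample(c("+", "-"), n, replace = TRUE)
        gr <- GRanges(names(L)[ci], IRanges(starts + 1L, width = lens),
            strand = std, seqinfo = chroms)
        mcols(gr)$gene_id <- sprintf("gene_%05d", gi + seq_len(n))
        mcols(gr)$tss <- ifelse(std == "+", starts, starts + lens)
        gi <- gi + n
        out[[ci]] <- gr
    }
    unlist(GRangesList(out[!vapply(out, is.null, TRUE)]))
}

#' Simulate two differential-expression tables with planted structure
#'
#' Both tables cover every annotated gene.  Planted DE genes satisfy
#' \code{|log2fc| > log2(1.5)} and \code{p_adj < 0.05} strictly; all other
#' genes fail the fold-change threshold.  `sharedFrac` of each table's DE
#' genes are common to both and `concordantFrac` of the shared genes agree in
#' sign (`downFrac` of those down in both).
#'
#' @param cfg a [SimConfig-class].
#' @param genes gene `GRanges` from [simulateGeneAnnotation()].
#' @return list with `a`, `b` (data.frames gene_id, log2fc, p_adj) and
#'   `truth` (list: deA, deB, shared, concordant gene ids).
#' @export
simulateDETables <- function(cfg, genes) {
    set.seed(subSeeds(cfg@seed, .SEED_DE)[.SEED_DE])
    ids <- mcols(genes)$gene_id
    nDE <- cfg@nDE
    nShared <- round(cfg@sharedFrac * nDE)
    if (abs(cfg@sharedFrac * nDE - nShared) > 1e-9)
        warning("sharedFrac * nDE is not integral; rounded to ", nShared)
    if (2 * nDE - nShared > length(ids))
        stop("not enough genes for the requested DE plan")
    deA <- sample(ids, nDE)
    shared <- sample(deA, nShared)
    deB <- c(shared, sample(setdiff(ids, deA), nDE - nShared))
    nConc <- round(cfg@concordantFrac * nShared)
    concordant <- if (nConc > 0) sample(shared, nConc) else character(0)

    lfc <- function(n) log2(1.5) + stats::rexp(n, rate = 1 / cfg@log2fcMag)
    signA <- stats::setNames(sample(c(1, -1), nDE, replace = TRUE), deA)
    # concordant shared genes: draw the common sign with P(down) = downFrac
    signA[concordant] <- ifelse(
        stats::runif(length(concordant)) < cfg@downFrac, -1, 1)
    signB <- stats::setNames(sample(c(1, -1), nDE, replace = TRUE), deB)
    signB[concordant] <- signA[concordant]
    disc <- setdiff(shared, concordant)
    signB[disc] <- -signA[disc]

    mkTable <- function(de, signs) {
        isDE <- ids %in% de
        l2 <- numeric(length(ids))
        p <- numeric(length(ids))
        l2[isDE] <- unname(signs[ids[isDE]]) * lfc(sum(isDE))
        p[isDE] <- stats::runif(sum(isDE), 1e-8, 0.049)
        l2[!isDE] <- stats::runif(sum(!isDE), -0.95, 0.95) * log2(1.5)
        p[!isDE] <- stats::runif(sum(!isDE), 0.05, 1)
        data.frame(gene_id = ids, log2fc = l2, p_adj = p,
            stringsAsFactors = FALSE)
    }
    list(a = mkTable(deA, signA), b = mkTable(deB, signB),
        truth = list(deA = sort(deA), deB = sort(deB),
            shared = sort(shared), concordant = sort(concordant)))
}

#' Simulate dual-luciferase reporter replicates
#'
#' Expected control-relative outputs are 1, effectA, effectB and
#' \code{(effectA + effectB - 1) * interaction}; each well receives
#' multiplicative log-normal noise with the configured CV (mean-preserving),
#' a per-well renilla reading, and firefly = relative x baseline x renilla.
#'
#' @param cfg a [SimConfig-class].
#' @param constructs named numeric vector, construct -> interaction
#'   multiplier.  The default pairs a synergistic divergent-GBM+E-box
#'   construct (the configured interaction) with an additive canonical
#'   construct.
#' @return reporter data.frame (construct, condition, replicate, firefly,
#'   renilla).
#' @export
simulateReporterData <- function(cfg,
        constructs = c(dGBM_Ebox = cfg@interaction, cGBM_Ebox = 1)) {
    set.seed(subSeeds(cfg@seed, .SEED_REPORTER)[.SEED_REPORTER])
    sig <- sqrt(log(1 + cfg@reporterCV^2))
    noise <- function(n) if (sig == 0) rep(1, n) else
        exp(stats::rnorm(n, -sig^2 / 2, sig))
    rows <- list()
    for (cst in names(constructs)) {
        rel <- c(control = 1, A = cfg@effectA, B = cfg@effectB,
            AB = (cfg@effectA + cfg@effectB - 1) * constructs[[cst]])
        for (cond in names(rel)) {
            ren <- 1000 * noise(cfg@nRep)
            ff <- cfg@reporterBaseline * rel[[cond]] * noise(cfg@nRep) * ren
            rows[[length(rows) + 1L]] <- data.frame(construct = cst,
                condition = cond, replicate = seq_len(cfg@nRep),
                firefly = ff, renilla = ren, stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, rows)
}

# jittered replicate of a peak set (edges moved by up to `jitter` bp) plus a
# fraction of replicate-private noise peaks
.jitterReplicate <- function(peaks, chroms, jitter = 20L, noiseFrac = 0.05) {
    n <- length(peaks)
    dS <- sample(seq(-jitter, jitter), n, replace = TRUE)
    dE <- sample(seq(-jitter, jitter), n, replace = TRUE)
    s <- pmax(1L, start(peaks) + dS)
    e <- pmin(seqlengths(chroms)[as.character(seqnames(peaks))],
        end(peaks) + dE)
    e <- pmax(e, s + 49L)
    rep <- GRanges(seqnames(peaks), IRanges(s, e), seqinfo = chroms)
    nNoise <- round(noiseFrac * n)
    if (nNoise > 0) {
        noise <- .placeUniform(.peakLens(nNoise, 200, 30), chroms)
        rep <- c(rep, noise)
    }
    BiocGenerics::sort(rep, ignore.strand = TRUE)
}

#' Simulate marker gene sets enriched near overlapping peaks
#'
#' @param cfg a [SimConfig-class].
#' @param genes gene `GRanges`.
#' @param proximalGenes gene ids near the planted overlapping peaks.
#' @param enrichedFrac fraction of the enriched cluster's markers drawn from
#'   `proximalGenes` (default 0.6); the background cluster is drawn uniformly.
#' @param nMarkers markers per cluster (default 50).
#' @return data.frame: cluster, gene_id.
#' @export
simulateMarkerSets <- function(cfg, genes, proximalGenes,
        enrichedFrac = 0.6, nMarkers = 50L) {
    set.seed(subSeeds(cfg@seed, .SEED_MARKERS)[.SEED_MARKERS])
    ids <- mcols(genes)$gene_id
    proximalGenes <- intersect(proximalGenes, ids)
    nProx <- min(round(enrichedFrac * nMarkers), length(proximalGenes))
    enriched <- c(sample(proximalGenes, nProx),
        sample(setdiff(ids, proximalGenes), nMarkers - nProx))
    background <- sample(ids, nMarkers)
    data.frame(
        cluster = rep(c("cluster_enriched", "cluster_background"),
            each = nMarkers),
        gene_id = c(enriched, background), stringsAsFactors = FALSE)
}

#' Simulate a complete study and write it to disk
#'
#' Orchestrates all generators under the master seed and writes: genome FASTA,
#' chromosome sizes, per-replicate and final BED peak files for both factors,
#' the gene annotation, two DE tables, marker sets, reporter measurements, the
#' bundled PWM, and `truth.json` recording the seed and every planted
#' quantity.
#'
#' @param cfg a [SimConfig-class].
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with all in-memory objects (chroms, store, peaks,
#'   truth, ledger, genes, de, markers, reporter, paths).
#' @export
simulateStudy <- function(cfg, outdir) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    gen <- simulateGenome(cfg)
    pk <- simulatePeakSets(cfg, gen$chroms)
    plan <- planPeakMotifs(cfg, pk$a, pk$truth$planted_overlap)
    emb <- embedMotifs(gen$store, pk$a, plan,
        seed = subSeeds(cfg@seed, .SEED_EMBED)[.SEED_EMBED] + 1L)
    genes <- simulateGeneAnnotation(cfg, gen$chroms)
    de <- simulateDETables(cfg, genes)
    reporter <- simulateReporterData(cfg)

    ovPeaks <- pk$a[pk$truth$planted_overlap]
    nearOv <- nearestGenes(ovPeaks, genes)
    proximal <- sort(unique(stats::na.omit(c(nearOv$upstream_gene,
        nearOv$downstream_gene))))
    markers <- simulateMarkerSets(cfg, genes, proximal)

    set.seed(subSeeds(cfg@seed, .SEED_REPL)[.SEED_REPL])
    reps <- list(a_rep1 = .jitterReplicate(pk$a, gen$chroms),
        a_rep2 = .jitterReplicate(pk$a, gen$chroms),
        b_rep1 = .jitterReplicate(pk$b, gen$chroms),
        b_rep2 = .jitterReplicate(pk$b, gen$chroms))

    paths <- list(
        genome = file.path(outdir, "genome.fa"),
        sizes = file.path(outdir, "chrom_sizes.tsv"),
        peaksA = file.path(outdir, "peaks_a.bed"),
        peaksB = file.path(outdir, "peaks_b.bed"),
        genes = file.path(outdir, "genes.tsv"),
        deA = file.path(outdir, "de_a.tsv"),
        deB = file.path(outdir, "de_b.tsv"),
        markers = file.path(outdir, "markers.tsv"),
        reporter = file.path(outdir, "reporter.tsv"),
        pwm = file.path(outdir, "gbm.pwm"),
        truth = file.path(outdir, "truth.json"))
    writeXStringSet(emb$store, paths$genome)
    writeChromSizes(gen$chroms, paths$sizes)
    writePeaks(pk$a, paths$peaksA)
    writePeaks(pk$b, paths$peaksB)
    for (nm in names(reps))
        writePeaks(reps[[nm]],
            file.path(outdir, paste0("peaks_", nm, ".bed")))
    writeGeneAnnotation(genes, paths$genes)
    utils::write.table(de$a, paths$deA, sep = "\t", quote = FALSE,
        row.names = FALSE)
    utils::write.table(de$b, paths$deB, sep = "\t", quote = FALSE,
        row.names = FALSE)
    utils::write.table(markers, paths$markers, sep = "\t", quote = FALSE,
        row.names = FALSE)
    utils::write.table(reporter, paths$reporter, sep = "\t", quote = FALSE,
        row.names = FALSE)
    file.copy(system.file("extdata", "gbm_synthetic.pwm",
        package = "comotif", mustWork = TRUE), paths$pwm, overwrite = TRUE)
    truth <- list(seed = cfg@seed,
        overlap_frac = cfg@overlapFrac,
        n_peaks_a = cfg@nPeaksA, n_peaks_b = cfg@nPeaksB,
        planted_overlap = pk$truth$peak[pk$truth$planted_overlap],
        class_plan = plan,
        motif_ledger = emb$ledger,
        de = de$truth,
        reporter = list(effect_a = cfg@effectA, effect_b = cfg@effectB,
            interaction = cfg@interaction, cv = cfg@reporterCV,
            n_rep = cfg@nRep))
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
    invisible(list(cfg = cfg, chroms = gen$chroms, store = emb$store,
        peaksA = pk$a, peaksB = pk$b, truth = pk$truth, plan = plan,
        ledger = emb$ledger, genes = genes, de = de, markers = markers,
        reporter = reporter, replicates = reps, paths = paths))
}
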