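#' @import methods
#' @importFrom S4Vectors isSingleNumber isSingleString
NULL

#' Position probability matrix with fraction-of-maximum scoring
#'
#' A position probability matrix (PPM) over \{A,C,G,T\}, stored one row per
#' motif position, together with the derived per-position log-odds against a
#' uniform background and the minimal/maximal achievable log-odds sums.  The
#' min/max range supports the fraction-of-maximum normalisation used to call
#' motif matches: a window scores \code{(raw - scoreMin) / (scoreMax - scoreMin)}.
#'
#' @slot motifID single string identifying the motif.
#' @slot probs numeric matrix, L positions x 4 bases (columns A,C,G,T), each
#'   row summing to 1 after pseudocount renormalisation.
#' @slot pseudocount pseudocount added to each probability before
#'   renormalisation (default 1e-3).
#' @slot logOdds L x 4 matrix of \code{log(prob / 0.25)}.
#' @slot scoreMin,scoreMax minimal and maximal achievable log-odds sums.
#' @seealso [readPWM()], [pwMatrix()], [scanPWM()]
#' @exportClass PWMatrix
setClass("PWMatrix",
    slots = c(
        motifID = "character",
        probs = "matrix",
        pseudocount = "numeric",
        logOdds = "matrix",
        scoreMin = "numeric",
        scoreMax = "numeric"
    )
)

setValidity("PWMatrix", function(object) {
    p <- object@probs
    if (!is.numeric(p) || ncol(p) != 4L)
        return("'probs' must be a numeric L x 4 matrix")
    if (nrow(p) < 1L)
        return("'probs' must have at least one position")
    if (!identical(colnames(p), c("A", "C", "G", "T")))
        return("'probs' columns must be named A, C, G, T")
    if (any(p < 0))
        return("probabilities must be non-negative")
    if (any(abs(rowSums(p) - 1) > 1e-6))
        return("each position of 'probs' must sum to 1 (+/- 1e-6)")
    if (object@scoreMin > object@scoreMax + 1e-12)
        return("scoreMin must not exceed scoreMax")
    TRUE
})

#' Canonical k-mer census
#'
#' Occurrence counts of k-mers collapsed onto canonical representatives: each
#' window of each scanned sequence contributes exactly one count to the
#' lexicographic minimum of the k-mer and its reverse complement, so a
#' palindromic window is counted once, never twice.  Only observed k-mers are
#' stored; [kmerRank()] ranks them and places absent k-mers after all present
#' ones.
#'
#' @slot k word size.
#' @slot counts named integer vector, canonical k-mer -> count (> 0).
#' @slot totalPositions total number of windows scanned, i.e.
#'   \code{sum(pmax(0, width - k + 1))} over the input sequences; counts sum to
#'   at most this (windows containing N are skipped).
#' @seealso [countKmers()], [kmerRank()], [canonicalKmer()]
#' @exportClass KmerCensus
setClass("KmerCensus",
    slots = c(
        k = "integer",
        counts = "integer",
        totalPositions = "numeric"
    )
)

setValidity("KmerCensus", function(object) {
    if (length(object@k) != 1L || object@k < 1L)
        return("'k' must be a single positive integer")
    cnt <- object@counts
    if (length(cnt) && is.null(names(cnt)))
        return("'counts' must be named by canonical k-mer")
    if (any(cnt < 0L))
        return("counts must be non-negative")
    if (length(cnt) && any(nchar(names(cnt)) != object@k))
        return("all k-mer names must have length k")
    if (sum(as.numeric(cnt)) > object@totalPositions + 1e-9)
        return("counts must sum to at most totalPositions")
    TRUE
})

#' Permutation enrichment result
#'
#' Result of a permutation test: the observed statistic, the permutation-null
#' mean and standard deviation, fold enrichment, a z score, and both the
#' empirical p-value \code{(1 + #null >= obs) / (1 + nPerm)} and the upper
#' normal-tail p-value at z (which can express extreme significance beyond the
#' Monte-Carlo floor).
#'
#' @slot observed observed statistic (an overlap or intersection count).
#' @slot nullMean,nullSd moments of the permutation null.
#' @slot fold \code{observed / nullMean} (0 when the null mean is 0).
#' @slot z standardised observed statistic.
#' @slot pEmpirical empirical upper-tail p-value, in (0, 1].
#' @slot pNormal upper normal-tail p-value at z.
#' @slot nPerm number of permutations.
#' @slot seed RNG seed used.
#' @seealso [permutationOverlapTest()], [genesetProximityEnrichment()]
#' @exportClass EnrichResult
setClass("EnrichResult",
    slots = c(
        observed = "numeric",
        nullMean = "numeric",
        nullSd = "numeric",
        fold = "numeric",
        z = "numeric",
        pEmpirical = "numeric",
        pNormal = "numeric",
        nPerm = "integer",
        seed = "integer"
    )
)

setValidity("EnrichResult", function(object) {
    if (object@fold < 0)
        return("'fold' must be non-negative")
    if (object@nullSd < 0)
        return("'nullSd' must be non-negative")
    if (object@pEmpirical <= 0 || object@pEmpirical > 1)
        return("'pEmpirical' must lie in (0, 1]")
    if (object@nPerm < 1L)
        return("'nPerm' must be positive")
    TRUE
})

#' Spacing/orientation grid for composite motif sites
#'
#' Tabulation of motif-pair configurations: counts indexed by orientation of
#' the PWM hit (\code{GBM+} or \code{GBM-}; the E-box pattern CANNTG is its own
#' reverse complement and contributes no strand) and by the signed edge-to-edge
#' gap between the two motifs, over gaps in \code{[-window, window]}.
#'
#' @slot counts integer matrix, 2 orientations x (2*window + 1) gaps; rownames
#'   \code{c("GBM+", "GBM-")}, colnames the gaps.
#' @slot window maximum absolute gap tabulated, in bp.
#' @slot total total number of pairs (sum of counts).
#' @slot nPeaksWithPair number of distinct peaks contributing at least one pair.
#' @seealso [compositeSites()], [spacingGrid()], [maxConfigFraction()],
#'   [configEnrichmentTest()]
#' @exportClass PairGrid
setClass("PairGrid",
    slots = c(
        counts = "matrix",
        window = "integer",
        total = "integer",
        nPeaksWithPair = "integer"
    )
)

setValidity("PairGrid", function(object) {
    cnt <- object@counts
    if (!identical(rownames(cnt), c("GBM+", "GBM-")))
        return("'counts' rows must be GBM+ and GBM-")
    if (ncol(cnt) != 2L * object@window + 1L)
        return("'counts' must have 2*window + 1 gap columns")
    if (any(cnt < 0))
        return("counts must be non-negative")
    if (sum(cnt) != object@total)
        return("'total' must equal sum(counts)")
    TRUE
})

#' Reporter synergy statistic
#'
#' Per-construct summary of a dual-luciferase synergy analysis on the
#' control-normalised scale: condition means, the additive expectation
#' \code{mean(A) + mean(B) - 1}, the excess of the combined condition over that
#' expectation, and a one-sided p-value for excess > 0.
#'
#' @slot construct construct identifier.
#' @slot conditionMeans named numeric vector of mean relative outputs for
#'   control, A, B, AB (control = 1 by construction).
#' @slot expectedAdditive additive expectation for AB.
#' @slot excess \code{mean(AB) - expectedAdditive}.
#' @slot statistic t-type statistic for the excess (delta method) or NA for the
#'   bootstrap method.
#' @slot df Welch-Satterthwaite degrees of freedom (delta method) or NA.
#' @slot pSynergy one-sided p-value for excess > 0.
#' @slot method \code{"delta"} or \code{"bootstrap"}.
#' @slot comparisons data.frame of pairwise Welch comparisons (see
#'   [conditionComparisons()]), possibly empty.
#' @seealso [synergyTest()], [normalizeReporter()]
#' @exportClass SynergyStat
setClass("SynergyStat",
    slots = c(
        construct = "character",
        conditionMeans = "numeric",
        expectedAdditive = "numeric",
        excess = "numeric",
        statistic = "numeric",
        df = "numeric",
        pSynergy = "numeric",
        method = "character",
        comparisons = "data.frame"
    )
)

setValidity("SynergyStat", function(object) {
    if (!all(c("control", "A", "B", "AB") %in% names(object@conditionMeans)))
        return("conditionMeans must cover control, A, B, AB")
    if (!is.na(object@pSynergy) &&
        (object@pSynergy < 0 || object@pSynergy > 1))
        return("'pSynergy' must lie in [0, 1]")
    TRUE
})

#' Simulation configuration
#'
#' Parameters of the synthetic-data generator.  The defaults encode the study
#' conditions the pipeline is designed around: two factors whose peak sets
#' overlap for 60% of the first factor's peaks, overlapping peaks dominated by
#' divergent Gli-binding motifs (85% dGBM / 5% cGBM / 10% neither),
#' factor-A-only peaks carrying the canonical motif in 16% of cases, two
#' differential-expression tables sharing half their DE genes with fully
#' concordant directions, and reporter assays with two-fold single-factor
#' effects.  See the methods vignette for the rationale behind each default.
#'
#' @slot seed master RNG seed.
#' @slot nChrom,chromLen number and length (bp) of simulated chromosomes.
#' @slot gc genome GC fraction.
#' @slot nPeaksA,nPeaksB peak counts for factors A and B.
#' @slot overlapFrac fraction of A peaks planted to overlap a B peak.
#' @slot peakLenMean,peakLenSd peak length distribution (bp; truncated normal).
#' @slot classProbsOverlap,classProbsAOnly motif-class probabilities
#'   (cGBM/dGBM/neither) for overlapping and A-only peaks.
#' @slot eboxProb probability that an embedded peak also receives an E-box.
#' @slot eboxGap signed edge-to-edge gap between the GBM and the planted E-box,
#'   or NA to draw uniformly within \code{eboxWindow}.
#' @slot eboxWindow maximum absolute gap for uniform E-box placement (bp).
#' @slot nGenes number of annotated genes.
#' @slot geneLenMin,geneLenMax gene body length range (bp).
#' @slot nDE planted DE genes per condition.
#' @slot sharedFrac fraction of DE genes shared between the two tables.
#' @slot concordantFrac fraction of shared DE genes with matching sign.
#' @slot downFrac fraction of concordant shared genes that are down in both.
#' @slot log2fcMag mean extra |log2 fold change| above the threshold for
#'   planted DE genes.
#' @slot reporterBaseline,effectA,effectB,interaction reporter generator:
#'   control-relative means are 1, effectA, effectB and
#'   \code{(effectA + effectB - 1) * interaction}.
#' @slot reporterCV coefficient of variation of the multiplicative log-normal
#'   noise on each well.
#' @slot nRep replicate wells per condition.
#' @seealso [simConfig()], [simulateStudy()]
#' @exportClass SimConfig
setClass("SimConfig",
    slots = c(
        seed = "integer",
        nChrom = "integer",
        chromLen = "numeric",
        gc = "numeric",
        nPeaksA = "integer",
        nPeaksB = "integer",
        overlapFrac = "numeric",
        peakLenMean = "numeric",
        peakLenSd = "numeric",
        classProbsOverlap = "numeric",
        classProbsAOnly = "numeric",
        eboxProb = "numeric",
        eboxGap = "numeric",
        eboxWindow = "integer",
        nGenes = "integer",
        geneLenMin = "integer",
        geneLenMax = "integer",
        nDE = "integer",
        sharedFrac = "numeric",
        concordantFrac = "numeric",
        downFrac = "numeric",
        log2fcMag = "numeric",
        reporterBaseline = "numeric",
        effectA = "numeric",
        effectB = "numeric",
        interaction = "numeric",
        reporterCV = "numeric",
        nRep = "integer"
    )
)

setValidity("SimConfig", function(object) {
    fr <- c(
        gc = object@gc, overlapFrac = object@overlapFrac,
        eboxProb = object@eboxProb, sharedFrac = object@sharedFrac,
        concordantFrac = object@concordantFrac, downFrac = object@downFrac
    )
    bad <- names(fr)[fr < 0 | fr > 1]
    if (length(bad))
        return(sprintf("fraction parameter(s) outside [0,1]: %s",
            paste(bad, collapse = ", ")))
    for (nm in c("classProbsOverlap", "classProbsAOnly")) {
        p <- slot(object, nm)
        if (!all(c("cGBM", "dGBM", "neither") %in% names(p)))
            return(sprintf("'%s' must name cGBM, dGBM, neither", nm))
        if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
            return(sprintf("'%s' must be a probability vector summing to 1", nm))
    }
    if (object@nChrom < 1L || object@chromLen < 1000)
        return("need at least one chromosome of >= 1 kb")
    if (object@nPeaksA < 1L || object@nPeaksB < 1L)
        return("peak counts must be positive")
    if (object@peakLenMean <= 0 || object@peakLenSd < 0)
        return("peak length parameters must be positive")
    if (object@nDE > object@nGenes)
        return("nDE cannot exceed nGenes")
    if (object@reporterBaseline <= 0 || object@effectA <= 0 ||
        object@effectB <= 0 || object@interaction <= 0)
        return("reporter baseline/effects/interaction must be positive")
    if (object@reporterCV < 0)
        return("reporterCV must be non-negative")
    if (object@nRep < 2L)
        return("need at least two replicates per condition")
    TRUE
})
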