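#' @include AllClasses.R
NULL

#' Accessors for comotif result objects
#'
#' Small accessor family for the S4 result classes; prefer these over direct
#' slot access.
#'
#' @param object a comotif S4 object.
#' @param ... unused.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("observed", function(object, ...) standardGeneric("observed"))

#' @rdname accessors
#' @export
setGeneric("nullMean", function(object, ...) standardGeneric("nullMean"))

#' @rdname accessors
#' @export
setGeneric("nullSd", function(object, ...) standardGeneric("nullSd"))

#' @rdname accessors
#' @export
setGeneric("foldEnrichment",
    function(object, ...) standardGeneric("foldEnrichment"))

#' @rdname accessors
#' @export
setGeneric("zScore", function(object, ...) standardGeneric("zScore"))

#' Extract p-values from result objects
#'
#' @param object an [EnrichResult-class] or [SynergyStat-class].
#' @param type for enrichment results, \code{"empirical"} (Monte-Carlo) or
#'   \code{"normal"} (upper normal tail at z).
#' @return a single p-value.
#' @export
setGeneric("pValue", function(object, ...) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setGeneric("kmerCounts", function(object, ...) standardGeneric("kmerCounts"))

#' @rdname accessors
#' @export
setGeneric("motifID", function(object, ...) standardGeneric("motifID"))

#' @rdname accessors
#' @export
setGeneric("gridCounts", function(object, ...) standardGeneric("gridCounts"))

#' @rdname accessors
#' @export
setGeneric("gridFractions",
    function(object, ...) standardGeneric("gridFractions"))

#' @rdname accessors
#' @export
setGeneric("synergyExcess",
    function(object, ...) standardGeneric("synergyExcess"))

setMethod("observed", "EnrichResult", function(object, ...) object@observed)
setMethod("nullMean", "EnrichResult", function(object, ...) object@nullMean)
setMethod("nullSd", "EnrichResult", function(object, ...) object@nullSd)
setMethod("foldEnrichment", "EnrichResult", function(object, ...) object@fold)
setMethod("zScore", "EnrichResult", function(object, ...) object@z)

#' @rdname pValue
setMethod("pValue", "EnrichResult", function(object, type = c("empirical",
    "normal"), ...) {
    switch(match.arg(type), empirical = object@pEmpirical,
        normal = object@pNormal)
})

#' @rdname pValue
setMethod("pValue", "SynergyStat", function(object, ...) object@pSynergy)

setMethod("kmerCounts", "KmerCensus", function(object, ...) object@counts)
setMethod("motifID", "PWMatrix", function(object, ...) object@motifID)
setMethod("gridCounts", "PairGrid", function(object, ...) object@counts)

setMethod("gridFractions", "PairGrid", function(object, ...) {
    if (object@total == 0L) object@counts * 0 else object@counts / object@total
})

setMethod("synergyExcess", "SynergyStat", function(object, ...) object@excess)

setMethod("show", "PWMatrix", function(object) {
    cat(sprintf("PWMatrix '%s': %d positions, pseudocount %g\n",
        object@motifID, nrow(object@probs), object@pseudocount))
    cons <- paste(colnames(object@probs)[max.col(object@probs)], collapse = "")
    cat(sprintf("  consensus %s; log-odds range [%.3f, %.3f]\n",
        cons, object@scoreMin, object@scoreMax))
})

setMethod("show", "KmerCensus", function(object) {
    cat(sprintf("KmerCensus: k=%d, %d canonical k-mers observed, %d windows\n",
        object@k, length(object@counts), as.integer(object@totalPositions)))
    if (length(object@counts)) {
        top <- sort(object@counts, decreasing = TRUE)
        top <- top[seq_len(min(5L, length(top)))]
        cat("  top:", paste(sprintf("%s=%d", names(top), top),
            collapse = " "), "\n")
    }
})

setMethod("show", "EnrichResult", function(object) {
    cat(sprintf(paste0("EnrichResult: observed %g, null %.3f +/- %.3f ",
        "(n_perm=%d)\n  fold %.3f, z %.3f, p_empirical %.3g, p_normal %.3g\n"),
        object@observed, object@nullMean, object@nullSd, object@nPerm,
        object@fold, object@z, object@pEmpirical, object@pNormal))
})

setMethod("show", "PairGrid", function(object) {
    cat(sprintf(
        "PairGrid: window %d bp, %d pairs from %d peaks with >=1 pair\n",
        object@window, object@total, object@nPeaksWithPair))
    if (object@total > 0L) {
        mx <- maxConfigFraction(object)
        cat(sprintf("  max configuration: %s gap %+d, fraction %.4f\n",
            mx$orientation, mx$gap, mx$fraction))
    }
})

setMethod("show", "SynergyStat", function(object) {
    cm <- object@conditionMeans
    cat(sprintf("SynergyStat '%s' (%s method)\n", object@construct,
        object@method))
    cat(sprintf("  relative means: control=%.3f A=%.3f B=%.3f AB=%.3f\n",
        cm["control"], cm["A"], cm["B"], cm["AB"]))
    cat(sprintf("  additive expectation %.3f, excess %.3f, p_synergy %.3g\n",
        object@expectedAdditive, object@excess, object@pSynergy))
})

setMethod("show", "SimConfig", function(object) {
    cat(sprintf(paste0("SimConfig: seed %d; %d x %g bp chromosomes (GC %.2f)\n",
        "  peaks: A=%d B=%d, overlap fraction %.2f\n",
        "  genes: %d, DE %d/table (shared %.2f, concordant %.2f)\n",
        "  reporter: effects %.2f/%.2f, interaction %.2f, CV %.2f, n_rep %d\n"),
        object@seed, object@nChrom, object@chromLen, object@gc,
        object@nPeaksA, object@nPeaksB, object@overlapFrac,
        object@nGenes, object@nDE, object@sharedFrac, object@concordantFrac,
        object@effectA, object@effectB, object@interaction, object@reporterCV,
        object@nRep))
})
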