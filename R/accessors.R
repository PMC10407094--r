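#' @rdname accessors
#' @name accessors
#' @title Accessors for dbsa result objects
#'
#' @description Small accessor generics so downstream code never touches
#' slots directly: \code{tScores} returns the named per-feature t vector
#' of a \linkS4class{ContrastProfile}; \code{signatureSets} the
#' increased/decreased named vectors of a \linkS4class{DiseaseSignature};
#' \code{reversalScore}, \code{enrichmentCurves} and \code{pValue} the
#' corresponding pieces of screen and DRFA results;
#' \code{discriminationPercent} and \code{recoveryPercent} the headline
#' indices; \code{sampleGroups} the group factor of a
#' \linkS4class{BehaviorExperiment}.
#'
#' @param object a dbsa S4 object.
#' @return See each method's description.
#' @aliases tScores signatureSets reversalScore enrichmentCurves pValue
#'   discriminationPercent recoveryPercent sampleGroups
#'   tScores,ContrastProfile-method signatureSets,DiseaseSignature-method
#'   reversalScore,EnrichmentResult-method
#'   enrichmentCurves,EnrichmentResult-method
#'   pValue,EnrichmentResult-method pValue,DiscriminationResult-method
#'   pValue,RecoveryResult-method
#'   discriminationPercent,DiscriminationResult-method
#'   recoveryPercent,RecoveryResult-method
#'   sampleGroups,BehaviorExperiment-method
NULL

#' @rdname accessors
#' @export
setGeneric("tScores", function(object) standardGeneric("tScores"))
#' @rdname accessors
#' @export
setMethod("tScores", "ContrastProfile", function(object)
    setNames(object@t, object@feature))

#' @rdname accessors
#' @export
setGeneric("signatureSets", function(object) standardGeneric("signatureSets"))
#' @rdname accessors
#' @export
setMethod("signatureSets", "DiseaseSignature", function(object)
    list(increased = object@increased, decreased = object@decreased))

#' @rdname accessors
#' @export
setGeneric("reversalScore", function(object) standardGeneric("reversalScore"))
#' @rdname accessors
#' @export
setMethod("reversalScore", "EnrichmentResult", function(object)
    object@reversalScore)

#' @rdname accessors
#' @export
setGeneric("enrichmentCurves", function(object) standardGeneric("enrichmentCurves"))
#' @rdname accessors
#' @export
setMethod("enrichmentCurves", "EnrichmentResult", function(object)
    object@curves)

#' @rdname accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setMethod("pValue", "EnrichmentResult", function(object) object@pValue)
#' @rdname accessors
#' @export
setMethod("pValue", "DiscriminationResult", function(object) object@pValue)
#' @rdname accessors
#' @export
setMethod("pValue", "RecoveryResult", function(object) object@pValue)

#' @rdname accessors
#' @export
setGeneric("discriminationPercent",
    function(object) standardGeneric("discriminationPercent"))
#' @rdname accessors
#' @export
setMethod("discriminationPercent", "DiscriminationResult",
    function(object) object@indexPercent)

#' @rdname accessors
#' @export
setGeneric("recoveryPercent", function(object) standardGeneric("recoveryPercent"))
#' @rdname accessors
#' @export
setMethod("recoveryPercent", "RecoveryResult",
    function(object) object@recoveryPercent)

#' @rdname accessors
#' @export
setGeneric("sampleGroups", function(object) standardGeneric("sampleGroups"))
#' @rdname accessors
#' @export
setMethod("sampleGroups", "BehaviorExperiment", function(object)
    setNames(as.character(SummarizedExperiment::colData(object)$group),
             colnames(object)))

setMethod("show", "ContrastProfile", function(object) {
    cat("ContrastProfile:", object@groupA, "(n =", object@nA, ") vs",
        object@groupB, "(n =", object@nB, ")\n")
    cat(" ", length(object@feature), "features;",
        sum(object@zeroVariance), "zero-variance (t set to 0)\n")
    cat("  t range: [", round(min(object@t), 3), ",",
        round(max(object@t), 3), "]\n")
})

setMethod("show", "DiseaseSignature", function(object) {
    cat("DiseaseSignature:", length(object@increased), "increased /",
        length(object@decreased), "decreased features\n")
    sel <- object@selection
    if (length(sel))
        cat("  selection: k_per_tail =", sel$k_per_tail,
            ", min |t| =", sel$min_abs_t, "\n")
    if (length(object@increased))
        cat("  top increased:", paste(head(names(object@increased), 3),
            collapse = ", "), "\n")
    if (length(object@decreased))
        cat("  top decreased:", paste(head(names(object@decreased), 3),
            collapse = ", "), "\n")
})

setMethod("show", "DrugRanking", function(object) {
    cat("DrugRanking:", object@drugId,
        if (!is.na(object@dose)) paste0("@ ", object@dose, " mg/kg"),
        "-", length(object@feature), "ranked features\n")
})

setMethod("show", "EnrichmentResult", function(object) {
    cat("EnrichmentResult:", object@drugId,
        if (!is.na(object@dose)) paste0("@ ", object@dose, " mg/kg"), "\n")
    cat(sprintf("  ES(increased) = %.3f, ES(decreased) = %.3f, reversal = %.3f\n",
        object@esIncreased, object@esDecreased, object@reversalScore))
    if (!is.na(object@pValue))
        cat(sprintf("  permutation p = %.4g (%d permutations)\n",
            object@pValue, object@nPermutations))
})

setMethod("show", "DRFSpace", function(object) {
    cat("DRFSpace:", length(object@featureNames), "features ->",
        ncol(object@rotation), "decorrelated components\n")
    cat("  fitted on:", object@groupA, "vs", object@groupB,
        "; variance kept:", object@varianceKept, "\n")
})

setMethod("show", "DiscriminationResult", function(object) {
    cat(sprintf("DiscriminationResult: index = %.1f%% (%d subsamples, %s)\n",
        object@indexPercent, object@nSubsamples, object@classifier))
    if (!is.na(object@pValue))
        cat(sprintf("  subsampling p = %.4g\n", object@pValue))
})

setMethod("show", "RecoveryResult", function(object) {
    cat(sprintf("RecoveryResult: recovery = %.1f%% (%s along %s -> %s)\n",
        object@recoveryPercent, object@groups[3], object@groups[1],
        object@groups[2]))
    if (!is.na(object@pValue))
        cat(sprintf("  one-sided p = %.4g\n", object@pValue))
})

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:", object@nFeatures, "features (",
        object@nAffected, "affected, effect", object@effectSize, "SD ),",
        object@nPerGroup, "per group\n")
    cat("  library:", nrow(object@librarySpec), "drug-dose rows; seed",
        object@seed, "\n")
})
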