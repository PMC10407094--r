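#' @import methods
#' @importFrom stats cov p.adjust pt rnorm runif sd setNames var
#' @importFrom utils read.delim write.table head modifyList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame
NULL

#' BehaviorExperiment: a behavioral feature matrix with sample metadata
#'
#' Thin wrapper around \linkS4class{SummarizedExperiment} holding one
#' numeric assay named \code{"features"} with features as rows and animal
#' subjects as columns. \code{colData} carries the per-sample metadata;
#' a \code{group} column is mandatory, and \code{sex}, \code{age_months},
#' \code{treatment} and \code{dose_mg_per_kg} are recognised when present.
#'
#' Validity requires unique sample identifiers (colnames), unique feature
#' names (rownames) and all-finite feature values; apply
#' \code{\link{applyMissingPolicy}} before construction if the raw table
#' contains missing cells.
#'
#' @seealso \code{\link{readFeatureMatrix}}, \code{\link{featureTScores}}
#' @export
setClass("BehaviorExperiment", contains = "SummarizedExperiment")

setValidity("BehaviorExperiment", function(object) {
    msg <- character()
    if (!"features" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'features' is required")
    else {
        a <- SummarizedExperiment::assay(object, "features")
        if (!is.numeric(a))
            msg <- c(msg, "assay 'features' must be numeric")
        else if (any(!is.finite(a)))
            msg <- c(msg, "assay 'features' contains non-finite values; apply a missing-value policy first")
    }
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids (colnames) must be present and unique")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "feature names (rownames) must be present and unique")
    if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData must contain a 'group' column")
    if (length(msg)) msg else TRUE
})

#' ContrastProfile: per-feature Welch t statistics for a two-group contrast
#'
#' One t score per behavioral feature for a case-vs-control comparison
#' (disease model vs wild type, or drug-treated vs vehicle). The sign
#' convention is case minus control: positive t means the feature is
#' higher in \code{groupA}. Features with zero pooled standard error are
#' assigned t = 0 and flagged in \code{zeroVariance}.
#'
#' @slot feature character, feature names in original matrix order.
#' @slot t numeric, one finite Welch t per feature.
#' @slot zeroVariance logical flag per feature.
#' @slot groupA,groupB labels of the contrasted groups (A is the case).
#' @slot nA,nB group sizes.
#' @export
setClass("ContrastProfile",
    representation(feature = "character", t = "numeric",
                   zeroVariance = "logical",
                   groupA = "character", groupB = "character",
                   nA = "integer", nB = "integer"))

setValidity("ContrastProfile", function(object) {
    msg <- character()
    n <- length(object@feature)
    if (anyDuplicated(object@feature))
        msg <- c(msg, "feature names must be unique")
    if (length(object@t) != n || length(object@zeroVariance) != n)
        msg <- c(msg, "t and zeroVariance must match feature length")
    if (any(!is.finite(object@t)))
        msg <- c(msg, "t scores must be finite")
    if (object@nA < 2L || object@nB < 2L)
        msg <- c(msg, "each group needs at least 2 samples")
    if (length(msg)) msg else TRUE
})

#' DiseaseSignature: the target phenotype as ordered feature sets
#'
#' Top differential features of the disease model split by direction:
#' \code{increased} (t > 0, most increased first) and \code{decreased}
#' (t < 0, most decreased first), each a named numeric vector of t scores
#' ordered by |t| descending. \code{selection} records the rule used
#' (k per tail, |t| threshold, source contrast).
#'
#' @export
setClass("DiseaseSignature",
    representation(increased = "numeric", decreased = "numeric",
                   selection = "list"))

setValidity("DiseaseSignature", function(object) {
    msg <- character()
    up <- object@increased; dn <- object@decreased
    if (length(up) && (is.null(names(up)) || any(up <= 0)))
        msg <- c(msg, "increased set must be named and strictly positive")
    if (length(dn) && (is.null(names(dn)) || any(dn >= 0)))
        msg <- c(msg, "decreased set must be named and strictly negative")
    if (length(intersect(names(up), names(dn))))
        msg <- c(msg, "increased and decreased sets must be disjoint")
    if (length(up) > 1 && is.unsorted(-abs(up)))
        msg <- c(msg, "increased set must be ordered by |t| descending")
    if (length(dn) > 1 && is.unsorted(-abs(dn)))
        msg <- c(msg, "decreased set must be ordered by |t| descending")
    if (!length(up) && !length(dn))
        msg <- c(msg, "signature is empty (no qualifying features)")
    if (length(msg)) msg else TRUE
})

#' DrugRanking: a drug-vs-vehicle profile as a ranked feature list
#'
#' Features sorted by the drug's differential t score, most increased
#' first. The ranking is the substrate the running enrichment score walks.
#' Ties in score keep the stable original feature order (the enrichment
#' score depends on rank order, so the tie-break is part of the contract).
#'
#' @slot drugId compound identifier.
#' @slot dose dose in mg/kg (NA allowed for un-dosed profiles).
#' @slot feature features in rank order (score descending).
#' @slot score the corresponding non-increasing t scores.
#' @export
setClass("DrugRanking",
    representation(drugId = "character", dose = "numeric",
                   feature = "character", score = "numeric"))

setValidity("DrugRanking", function(object) {
    msg <- character()
    if (length(object@feature) != length(object@score))
        msg <- c(msg, "feature and score lengths differ")
    if (anyDuplicated(object@feature))
        msg <- c(msg, "duplicate features in ranking")
    if (length(object@score) > 1 && is.unsorted(-object@score))
        msg <- c(msg, "scores must be non-increasing")
    if (any(!is.finite(object@score)))
        msg <- c(msg, "scores must be finite")
    if (length(msg)) msg else TRUE
})

#' EnrichmentResult: two-set enrichment of a drug profile against a signature
#'
#' Extrema of the running enrichment curves for the signature's increased
#' and decreased sets on one drug ranking, the combined reversal score,
#' and (once \code{\link{permutationPValue}} has run) its permutation p.
#' \code{curves} holds one data.frame per set with columns
#' \code{position}, \code{running_es}, \code{theoretical_max}.
#'
#' @export
setClass("EnrichmentResult",
    representation(drugId = "character", dose = "numeric",
                   esIncreased = "numeric", esDecreased = "numeric",
                   reversalScore = "numeric", pValue = "numeric",
                   curves = "list", nPermutations = "integer",
                   seed = "integer"))

setValidity("EnrichmentResult", function(object) {
    msg <- character()
    for (nm in c("esIncreased", "esDecreased", "reversalScore")) {
        v <- slot(object, nm)
        if (length(v) != 1 || !is.finite(v) || abs(v) > 1 + 1e-12)
            msg <- c(msg, sprintf("%s must be a single value in [-1, 1]", nm))
    }
    p <- object@pValue
    if (length(p) == 1 && !is.na(p) && (p <= 0 || p > 1))
        msg <- c(msg, "pValue must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' DRFSpace: standardization plus decorrelating rotation
#'
#' Fitted on the pooled samples of two reference groups: per-feature
#' centering and scaling, then the eigenvectors of the pooled correlation
#' structure. Components are re-ranked by absolute between-group t on the
#' component scores (discriminant order); \code{componentSd} holds each
#' retained component's standard deviation on the pooled training data
#' so that projections can be whitened into the (affine-invariant)
#' pooled Mahalanobis geometry.
#'
#' @slot featureNames features the space was fitted on.
#' @slot center,scale per-feature standardization parameters.
#' @slot rotation p x k matrix with orthonormal columns, discriminant order.
#' @slot componentSd pooled-training SD of each retained component.
#' @slot componentT between-group Welch t of each retained component.
#' @slot eigenRank original variance rank of each retained component.
#' @slot varianceKept the fraction requested at fit time.
#' @slot groupA,groupB the reference group labels.
#' @export
setClass("DRFSpace",
    representation(featureNames = "character", center = "numeric",
                   scale = "numeric", rotation = "matrix",
                   componentSd = "numeric", componentT = "numeric",
                   eigenRank = "integer", varianceKept = "numeric",
                   groupA = "character", groupB = "character"))

setValidity("DRFSpace", function(object) {
    msg <- character()
    p <- length(object@featureNames)
    k <- ncol(object@rotation)
    if (nrow(object@rotation) != p)
        msg <- c(msg, "rotation rows must match featureNames")
    if (length(object@componentSd) != k || length(object@componentT) != k)
        msg <- c(msg, "componentSd/componentT must match retained components")
    if (k) {
        ortho <- crossprod(object@rotation)
        if (max(abs(ortho - diag(k))) > 1e-8)
            msg <- c(msg, "rotation columns must be orthonormal")
    }
    if (length(msg)) msg else TRUE
})

#' GroupCloud: 2D summary of a group in DRF space
#'
#' Mean and axis-aligned dispersion ellipses of one group on two chosen
#' discriminant components: the SD ellipse (outer) and the SEM ellipse
#' (inner, SD axes divided by sqrt(n) exactly).
#'
#' @export
setClass("GroupCloud",
    representation(label = "character", mean2d = "numeric",
                   sdAxes = "numeric", semAxes = "numeric",
                   n = "integer", components = "integer",
                   degenerate = "logical"))

#' DiscriminationResult: held-out separability of two groups
#'
#' Mean held-out accuracy of a nearest-centroid linear classifier over
#' repeated stratified subsamples in DRF space, expressed on the 50-100
#' scale (clamped at 50 = chance). \code{pValue} is NA until
#' \code{\link{discriminationPValue}} fills it in.
#'
#' @export
setClass("DiscriminationResult",
    representation(indexPercent = "numeric", pValue = "numeric",
                   nSubsamples = "integer", holdoutFraction = "numeric",
                   classifier = "character", seed = "integer",
                   accuracies = "numeric", clouds = "list"))

setValidity("DiscriminationResult", function(object) {
    if (object@indexPercent < 50 - 1e-9 || object@indexPercent > 100 + 1e-9)
        "indexPercent must lie in [50, 100]" else TRUE
})

#' RecoveryResult: treatment rescue along the model-to-control axis
#'
#' Scalar coordinates of every model, wild-type and test sample after
#' orthogonal projection onto the segment joining the model and WT group
#' means in (whitened) DRF space, scaled so the model mean is exactly 0
#' and the WT mean exactly 1. \code{recoveryPercent} is 100 x the test
#' group's mean coordinate clamped to [0, 1].
#'
#' @export
setClass("RecoveryResult",
    representation(recoveryPercent = "numeric", pValue = "numeric",
                   projections = "list", segment = "list",
                   groups = "character"))

setValidity("RecoveryResult", function(object) {
    if (object@recoveryPercent < 0 || object@recoveryPercent > 100)
        "recoveryPercent must lie in [0, 100]" else TRUE
})

#' SimulationConfig: ground-truth recipe for synthetic cohorts and libraries
#'
#' Describes a correlated Gaussian feature model (low-rank factors plus
#' independent noise), a planted disease effect on a feature subset, and
#' a drug library of reversers, mimics, partial reversers and nulls at
#' one or more doses. See \code{\link{simulationConfig}} for defaults.
#'
#' @export
setClass("SimulationConfig",
    representation(nFeatures = "integer", nAffected = "integer",
                   effectSize = "numeric", nFactors = "integer",
                   factorStrength = "numeric", nPerGroup = "integer",
                   noiseSd = "numeric", librarySpec = "data.frame",
                   seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (object@nAffected > object@nFeatures)
        msg <- c(msg, "nAffected cannot exceed nFeatures")
    if (object@nFactors >= object@nFeatures)
        msg <- c(msg, "factor count must be below nFeatures")
    if (any(c(object@nFeatures, object@nAffected, object@nPerGroup) < 1))
        msg <- c(msg, "all sizes must be positive")
    if (object@noiseSd <= 0)
        msg <- c(msg, "noiseSd must be positive")
    ls <- object@librarySpec
    need <- c("drug_id", "dose", "archetype", "strength")
    if (!all(need %in% names(ls)))
        msg <- c(msg, paste("librarySpec needs columns:", paste(need, collapse = ", ")))
    else {
        bad <- setdiff(unique(ls$archetype), c("reverser", "mimic", "null", "partial"))
        if (length(bad))
            msg <- c(msg, paste("unknown archetype:", paste(bad, collapse = ", ")))
        if (any(ls$strength < 0 | ls$strength > 1))
            msg <- c(msg, "strength must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
})
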