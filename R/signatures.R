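#' Per-feature Welch t statistics between two sample groups
#'
#' Computes one unequal-variance (Welch) two-sample t statistic per
#' behavioral feature, with \code{groupA} (the case: disease model or
#' drug-treated) minus \code{groupB} (the control) in the numerator, so
#' positive t means higher in the case group. Features whose pooled
#' standard error is zero (constant in both groups) get t = 0 and are
#' flagged rather than producing NaN/Inf: large behavioral batteries
#' routinely contain constant features.
#'
#' @param be a \linkS4class{BehaviorExperiment}.
#' @param groupA,groupB sample selectors: a group label, a named list of
#'   metadata filters (e.g. \code{list(group = "HD", sex = "F")}), a
#'   character vector of sample ids, or a logical vector.
#' @return a \linkS4class{ContrastProfile}.
#' @examples
#' vals <- rbind(a = c(1, 2, 3), b = c(4, 5, 6))
#' be <- BehaviorExperiment(
#'     matrix(c(1, 2, 3, 4, 5, 6), 6, 1, dimnames = list(paste0("s", 1:6), "f")),
#'     data.frame(group = rep(c("A", "B"), each = 3)))
#' tScores(featureTScores(be, "A", "B"))  # -3.674
#' @export
featureTScores <- function(be, groupA, groupB) {
    ia <- selectSamples(be, groupA, "groupA")
    ib <- selectSamples(be, groupB, "groupB")
    if (length(intersect(ia, ib)))
        stop("groupA and groupB selections overlap")
    if (length(ia) < 2) stop("groupA has fewer than 2 samples")
    if (length(ib) < 2) stop("groupB has fewer than 2 samples")
    x <- SummarizedExperiment::assay(be, "features")
    t <- welchStatistic(x[, ia, drop = FALSE], x[, ib, drop = FALSE])
    methods::new("ContrastProfile",
        feature = rownames(be), t = unname(t$t),
        zeroVariance = unname(t$zeroVariance),
        groupA = selectorLabel(groupA), groupB = selectorLabel(groupB),
        nA = length(ia), nB = length(ib))
}

# Vectorised Welch t over the rows of two feature x sample matrices.
welchStatistic <- function(xa, xb) {
    na <- ncol(xa); nb <- ncol(xb)
    ma <- rowMeans(xa); mb <- rowMeans(xb)
    va <- rowSums((xa - ma)^2) / (na - 1)
    vb <- rowSums((xb - mb)^2) / (nb - 1)
    se2 <- va / na + vb / nb
    zero <- se2 == 0
    t <- ifelse(zero, 0, (ma - mb) / sqrt(ifelse(zero, 1, se2)))
    list(t = t, zeroVariance = zero)
}

#' Extract the disease signature from a contrast profile
#'
#' Selects the target phenotype: up to \code{kPerTail} features with the
#' largest positive t (the increased set) and up to \code{kPerTail} with
#' the most negative t (the decreased set), each subject to
#' \code{|t| >= minAbsT} and ordered by |t| descending. Zero-variance
#' features never qualify. When fewer features qualify than requested,
#' the sets are simply shorter; if both sets come out empty the profile
#' carries no signature and an error is raised.
#'
#' @param profile a \linkS4class{ContrastProfile} (disease model vs WT).
#' @param kPerTail maximum features per direction (default 20).
#' @param minAbsT minimum absolute t to qualify (default 0).
#' @return a \linkS4class{DiseaseSignature}.
#' @export
buildDiseaseSignature <- function(profile, kPerTail = 20, minAbsT = 0) {
    stopifnot(is(profile, "ContrastProfile"))
    if (kPerTail < 1) stop("kPerTail must be >= 1")
    if (minAbsT < 0) stop("minAbsT must be >= 0")
    t <- setNames(profile@t, profile@feature)
    t[profile@zeroVariance] <- 0
    up <- t[t > 0 & t >= minAbsT]
    up <- up[order(up, decreasing = TRUE)]
    dn <- t[t < 0 & t <= -minAbsT]
    dn <- dn[order(abs(dn), decreasing = TRUE)]
    up <- up[seq_len(min(kPerTail, length(up)))]
    dn <- dn[seq_len(min(kPerTail, length(dn)))]
    if (!length(up) && !length(dn))
        stop("no signature: no feature passes the selection rule")
    methods::new("DiseaseSignature",
        increased = up, decreased = dn,
        selection = list(k_per_tail = kPerTail, min_abs_t = minAbsT,
                         contrast = paste(profile@groupA, "vs", profile@groupB),
                         n_a = profile@nA, n_b = profile@nB))
}

#' Build a ranked drug profile
#'
#' Orders a drug-vs-vehicle contrast by t score descending to form the
#' ranking the enrichment score walks. Score ties keep the original
#' feature order (stable sort) because the running sum depends on rank
#' order.
#'
#' @param profile a \linkS4class{ContrastProfile} (drug vs vehicle), or a
#'   named numeric score vector.
#' @param drugId compound identifier.
#' @param dose dose in mg/kg (NA if not applicable).
#' @return a \linkS4class{DrugRanking}.
#' @export
drugRanking <- function(profile, drugId, dose = NA_real_) {
    s <- if (is(profile, "ContrastProfile")) tScores(profile)
         else profile
    if (is.null(names(s))) stop("scores must be named by feature")
    names(s) <- trimws2(names(s))
    ord <- order(-s)             # radix stable sort: ties keep input order
    methods::new("DrugRanking", drugId = as.character(drugId),
        dose = as.numeric(dose), feature = names(s)[ord],
        score = unname(s[ord]))
}
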