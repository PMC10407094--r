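# Two-tailed enrichment of a disease signature in a ranked drug profile.
#
# The running sum is the weighted Kolmogorov-Smirnov walk used in gene-set
# enrichment: descending the ranking, a set member ("hit") at rank i adds
# |score_i|^p / sum_hits |score|^p, a non-member subtracts 1/(n - m).
# Both masses integrate to 1, so the curve ends at 0; the enrichment
# score is the signed extremum. The two signature sets (increased and
# decreased in the disease model) are evaluated in a single pass over the
# same ranking and combined into one reversal score.

# Signed extremum of a running curve. When the positive peak and the
# negative trough have (numerically) equal magnitude the positive one is
# preferred; the small tolerance keeps the choice stable under the
# last-bit accumulation differences different summation orders produce.
pickExtremum <- function(es) {
    mx <- max(es)
    mn <- min(es)
    if (mx >= -mn - 1e-9) mx else mn
}

# Running curve + extremum on a pre-sorted score vector. hit is logical.
esWalk <- function(score, hit, weightExponent) {
    n <- length(score)
    m <- sum(hit)
    w <- abs(score)^weightExponent
    sw <- sum(w[hit])
    steps <- numeric(n)
    steps[hit] <- if (sw > 0) w[hit] / sw else 1 / m
    if (m < n) steps[!hit] <- -1 / (n - m)
    pickExtremum(cumsum(steps))
}

esWalkCurve <- function(score, hit, weightExponent) {
    n <- length(score)
    m <- sum(hit)
    w <- abs(score)^weightExponent
    sw <- sum(w[hit])
    hitSteps <- if (sw > 0) w[hit] / sw else rep(1 / m, m)
    steps <- numeric(n)
    steps[hit] <- hitSteps
    if (m < n) steps[!hit] <- -1 / (n - m)
    es <- cumsum(steps)
    tmSteps <- numeric(n)
    tmSteps[seq_len(m)] <- sort(hitSteps, decreasing = TRUE)
    if (m < n) tmSteps[(m + 1):n] <- -1 / (n - m)
    list(curve = data.frame(position = seq_len(n), running_es = es,
                            theoretical_max = cumsum(tmSteps)),
         es = pickExtremum(es))
}

resolveSet <- function(ranking, featureSet, what = "feature set") {
    featureSet <- trimws2(featureSet)
    if (!length(featureSet)) stop(what, " is empty")
    missing <- setdiff(featureSet, ranking@feature)
    if (length(missing))
        stop(what, " member(s) absent from ranking: ",
             paste(missing, collapse = ", "))
    ranking@feature %in% featureSet
}

#' Running enrichment score of a feature set in a drug ranking
#'
#' Walks the ranking top to bottom accumulating weighted hit mass and
#' constant miss mass; returns the full running curve, the matching
#' theoretical-maximum curve (the walk the set would trace if its members
#' occupied the top ranks with their own weights) and the signed extremum.
#'
#' @param ranking a \linkS4class{DrugRanking}.
#' @param featureSet character vector of feature names; must be non-empty
#'   and fully contained in the ranking.
#' @param weightExponent non-negative exponent on |score| for hit
#'   weights; 1 (default) weights by score, 0 gives the classic
#'   equal-step Kolmogorov-Smirnov form.
#' @return list with \code{curve} (data.frame \code{position},
#'   \code{running_es}, \code{theoretical_max}) and \code{es} (extremum).
#' @export
runningEnrichmentScore <- function(ranking, featureSet, weightExponent = 1) {
    stopifnot(is(ranking, "DrugRanking"), weightExponent >= 0)
    hit <- resolveSet(ranking, featureSet)
    esWalkCurve(ranking@score, hit, weightExponent)
}

#' Two-set reversal enrichment of a signature in one drug profile
#'
#' Evaluates the running enrichment score of the signature's increased
#' and decreased sets on the same ranking in a single pass and combines
#' the two extrema into a reversal score:
#' \deqn{reversal = (ES_{decreased} - ES_{increased}) / 2}
#' when the extrema have opposite signs, and 0 when they share a sign
#' (both sets piling on the same end of the profile is not reversal; the
#' rule can be disabled with \code{sameSignZero = FALSE}). Positive
#' reversal means the drug pushes disease-increased features down and
#' disease-decreased features up. Signature features absent from the
#' ranking are dropped with a warning so heterogeneous libraries remain
#' screenable.
#'
#' @param ranking a \linkS4class{DrugRanking}.
#' @param signature a \linkS4class{DiseaseSignature}.
#' @param weightExponent see \code{\link{runningEnrichmentScore}}.
#' @param sameSignZero if TRUE (default), a same-sign extrema pair scores 0.
#' @return an \linkS4class{EnrichmentResult} with \code{pValue = NA}
#'   until \code{\link{permutationPValue}} is applied.
#' @export
enrichmentReversal <- function(ranking, signature, weightExponent = 1,
                               sameSignZero = TRUE) {
    stopifnot(is(ranking, "DrugRanking"), is(signature, "DiseaseSignature"))
    up <- intersect(names(signature@increased), ranking@feature)
    dn <- intersect(names(signature@decreased), ranking@feature)
    dropped <- length(signature@increased) + length(signature@decreased) -
        length(up) - length(dn)
    if (dropped > 0)
        warning(dropped, " signature feature(s) absent from ranking '",
                ranking@drugId, "' dropped")
    if (!length(up) && !length(dn))
        stop("no signature feature resolvable in ranking '",
             ranking@drugId, "'")
    emptyCurve <- list(curve = data.frame(position = integer(0),
        running_es = numeric(0), theoretical_max = numeric(0)), es = 0)
    upRes <- if (length(up))
        esWalkCurve(ranking@score, ranking@feature %in% up, weightExponent)
        else emptyCurve
    dnRes <- if (length(dn))
        esWalkCurve(ranking@score, ranking@feature %in% dn, weightExponent)
        else emptyCurve
    methods::new("EnrichmentResult",
        drugId = ranking@drugId, dose = ranking@dose,
        esIncreased = upRes$es, esDecreased = dnRes$es,
        reversalScore = combineES(upRes$es, dnRes$es, sameSignZero),
        pValue = NA_real_,
        curves = list(increased = upRes$curve, decreased = dnRes$curve),
        nPermutations = 0L, seed = NA_integer_)
}

combineES <- function(esUp, esDn, sameSignZero = TRUE) {
    if (sameSignZero && esUp * esDn > 0) 0 else (esDn - esUp) / 2
}

#' Permutation p-value for a reversal enrichment score
#'
#' Non-parametric significance of an observed reversal score: the
#' signature membership is permuted over the ranked features (the drug
#' ranking itself stays fixed), drawing disjoint random increased and
#' decreased sets of the observed sizes uniformly without replacement,
#' and the reversal score is recomputed for each draw. The add-one
#' estimator \eqn{p = (1 + \#\{perm \ge obs\}) / (B + 1)} is one-sided
#' toward reversal, so p is never smaller than \eqn{1/(B+1)}.
#'
#' @param ranking,signature as in \code{\link{enrichmentReversal}}.
#' @param result optional \linkS4class{EnrichmentResult} already computed
#'   for this pair (recomputed when NULL).
#' @param weightExponent,sameSignZero must match the observed statistic.
#' @param nPermutations number of random set pairs (default 1000).
#' @param seed integer seed (mandatory; every stochastic step is seeded).
#' @return the \linkS4class{EnrichmentResult} with \code{pValue},
#'   \code{nPermutations} and \code{seed} filled in.
#' @export
permutationPValue <- function(ranking, signature, result = NULL,
        weightExponent = 1, nPermutations = 1000, seed,
        sameSignZero = TRUE) {
    stopifnot(nPermutations >= 1)
    if (is.null(result))
        result <- suppressWarnings(enrichmentReversal(ranking, signature,
            weightExponent, sameSignZero))
    up <- intersect(names(signature@increased), ranking@feature)
    dn <- intersect(names(signature@decreased), ranking@feature)
    n <- length(ranking@feature)
    mU <- length(up); mD <- length(dn)
    if (mU + mD > n)
        stop("set sizes (", mU, " + ", mD,
             ") exceed ranking length; disjoint resampling impossible")
    score <- ranking@score
    perm <- withSeed(seed, vapply(seq_len(nPermutations), function(i) {
        idx <- sample.int(n, mU + mD)
        hitU <- logical(n); hitU[idx[seq_len(mU)]] <- TRUE
        hitD <- logical(n); hitD[idx[mU + seq_len(mD)]] <- TRUE
        combineES(if (mU) esWalk(score, hitU, weightExponent) else 0,
                  if (mD) esWalk(score, hitD, weightExponent) else 0,
                  sameSignZero)
    }, numeric(1)))
    p <- (1 + sum(perm >= result@reversalScore)) / (nPermutations + 1)
    methods::initialize(result, pValue = p,
        nPermutations = as.integer(nPermutations),
        seed = as.integer(seed))
}
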