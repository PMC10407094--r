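# Decorrelated Ranked Feature Analysis: a linear map to statistically
# independent feature combinations fitted on two reference groups,
# plus group-separation (Discrimination Index) and treatment-rescue
# (Recovery Index) statistics computed in that space.

#' Fit the decorrelated feature space on two reference groups
#'
#' Standardizes each feature on the pooled samples of the two groups,
#' eigendecomposes the pooled covariance of the standardized data, keeps
#' the smallest number of components whose variance share reaches
#' \code{varianceKept} (rank-deficient directions are always dropped),
#' and re-ranks the retained components by absolute between-group Welch t
#' on the component scores, so component 1 is the most discriminant
#' direction. The transformed pooled data has diagonal covariance by
#' construction, and the stored rotation has orthonormal columns.
#'
#' @param be a \linkS4class{BehaviorExperiment}.
#' @param groupA,groupB sample selectors (each must match >= 3 samples).
#' @param varianceKept fraction of pooled variance to retain, in (0, 1].
#' @return a \linkS4class{DRFSpace}.
#' @export
fitDRFSpace <- function(be, groupA, groupB, varianceKept = 0.95) {
    stopifnot(varianceKept > 0, varianceKept <= 1)
    ia <- selectSamples(be, groupA, "groupA")
    ib <- selectSamples(be, groupB, "groupB")
    if (length(ia) < 3 || length(ib) < 3)
        stop("each reference group needs >= 3 samples")
    X <- t(SummarizedExperiment::assay(be, "features")[, c(ia, ib),
                                                       drop = FALSE])
    center <- colMeans(X)
    scl <- apply(X, 2, sd)
    if (all(scl == 0)) stop("all features are constant; no space to fit")
    scl[scl == 0] <- 1
    Z <- scale(X, center = center, scale = scl)
    eig <- eigen(cov(Z), symmetric = TRUE)
    pos <- eig$values > max(eig$values) * 1e-10
    vals <- eig$values[pos]
    share <- cumsum(vals) / sum(vals)
    k <- which(share >= varianceKept - 1e-12)[1]
    V <- eig$vectors[, seq_len(k), drop = FALSE]
    scores <- Z %*% V
    grp <- rep(c(TRUE, FALSE), c(length(ia), length(ib)))
    tcomp <- welchStatistic(t(scores[grp, , drop = FALSE]),
                            t(scores[!grp, , drop = FALSE]))$t
    ord <- order(-abs(tcomp))
    methods::new("DRFSpace",
        featureNames = colnames(X), center = center, scale = scl,
        rotation = V[, ord, drop = FALSE],
        componentSd = sqrt(vals[seq_len(k)])[ord],
        componentT = tcomp[ord], eigenRank = as.integer(seq_len(k)[ord]),
        varianceKept = varianceKept,
        groupA = selectorLabel(groupA), groupB = selectorLabel(groupB))
}

#' Project samples into a fitted DRF space
#'
#' @param space a \linkS4class{DRFSpace}.
#' @param x a \linkS4class{BehaviorExperiment} or a samples-by-features
#'   numeric matrix covering the space's features.
#' @param whiten if TRUE (default) each component is scaled to unit
#'   pooled-training variance, putting the projection in the pooled
#'   Mahalanobis geometry (invariant under invertible affine maps of the
#'   raw features when all rank is retained); FALSE keeps the raw
#'   decorrelated scores.
#' @return samples x components numeric matrix in discriminant order.
#' @export
projectDRF <- function(space, x, whiten = TRUE) {
    if (is(x, "BehaviorExperiment"))
        x <- t(SummarizedExperiment::assay(x, "features"))
    x <- as.matrix(x)
    missing <- setdiff(space@featureNames, colnames(x))
    if (length(missing))
        stop("input lacks feature(s): ", paste(head(missing, 5), collapse = ", "))
    x <- x[, space@featureNames, drop = FALSE]
    Z <- scale(x, center = space@center, scale = space@scale)
    Y <- Z %*% space@rotation
    if (whiten) Y <- sweep(Y, 2, space@componentSd, "/")
    colnames(Y) <- paste0("DRF", seq_len(ncol(Y)))
    Y
}

# Mean held-out nearest-centroid accuracy over stratified random splits.
# Within each split the components are standardized by the training
# samples' within-class pooled SD (diagonal LDA); held-out samples never
# inform the metric, so the accuracy is unbiased under exchangeability.
holdoutAccuracies <- function(YA, YB, nSubsamples, holdoutFraction, seed) {
    nA <- nrow(YA); nB <- nrow(YB)
    tA <- min(max(1L, round(holdoutFraction * nA)), nA - 1L)
    tB <- min(max(1L, round(holdoutFraction * nB)), nB - 1L)
    if (nA < 2 || nB < 2)
        stop("degenerate holdout: need >= 2 samples per group")
    withSeed(seed, vapply(seq_len(nSubsamples), function(i) {
        hA <- sample.int(nA, tA); hB <- sample.int(nB, tB)
        trA <- YA[-hA, , drop = FALSE]
        trB <- YB[-hB, , drop = FALSE]
        cA <- colMeans(trA)
        cB <- colMeans(trB)
        df <- nrow(trA) + nrow(trB) - 2L
        s <- if (df >= 1) {
            sqrt((colSums(sweep(trA, 2, cA)^2) +
                  colSums(sweep(trB, 2, cB)^2)) / df)
        } else rep(1, ncol(YA))
        s[!is.finite(s) | s < 1e-12] <- 1
        test <- rbind(YA[hA, , drop = FALSE], YB[hB, , drop = FALSE])
        dA <- rowSums(sweep(sweep(test, 2, cA), 2, s, "/")^2)
        dB <- rowSums(sweep(sweep(test, 2, cB), 2, s, "/")^2)
        predA <- dA < dB | (dA == dB & stats::runif(nrow(test)) < 0.5)
        mean(predA == rep(c(TRUE, FALSE), c(tA, tB)))
    }, numeric(1)))
}

#' Discrimination Index: held-out separability of two groups
#'
#' Repeatedly holds out a stratified fraction of both groups, fits a
#' nearest-centroid linear classifier on the training samples in DRF
#' space (components standardized by the training within-class pooled
#' SD, i.e. a diagonal LDA rule), and scores accuracy on the held-out
#' samples.
#' The index is 100 x the mean accuracy, clamped below at 50: 50 means
#' no separation, 100 complete separability.
#'
#' @param be a \linkS4class{BehaviorExperiment}.
#' @param groupA,groupB sample selectors.
#' @param space optional pre-fitted \linkS4class{DRFSpace}; fitted on
#'   the two groups with \code{varianceKept} when NULL.
#' @param varianceKept used only when fitting internally.
#' @param nSubsamples number of random holdout splits (default 200).
#' @param holdoutFraction fraction of each group held out (default 0.5).
#' @param seed integer seed.
#' @return a \linkS4class{DiscriminationResult} (pValue NA; see
#'   \code{\link{discriminationPValue}}).
#' @export
discriminationIndex <- function(be, groupA, groupB, space = NULL,
        varianceKept = 0.95, nSubsamples = 200, holdoutFraction = 0.5,
        seed) {
    stopifnot(nSubsamples >= 1)
    if (is.null(space))
        space <- fitDRFSpace(be, groupA, groupB, varianceKept)
    YA <- projectDRF(space, be[, selectSamples(be, groupA, "groupA")])
    YB <- projectDRF(space, be[, selectSamples(be, groupB, "groupB")])
    acc <- holdoutAccuracies(YA, YB, nSubsamples, holdoutFraction, seed)
    clouds <- list(cloudFromScores(YA, selectorLabel(groupA)),
                   cloudFromScores(YB, selectorLabel(groupB)))
    methods::new("DiscriminationResult",
        indexPercent = max(50, 100 * mean(acc)), pValue = NA_real_,
        nSubsamples = as.integer(nSubsamples),
        holdoutFraction = holdoutFraction,
        classifier = "nearest-centroid", seed = as.integer(seed),
        accuracies = acc, clouds = clouds)
}

#' Subsampling p-value for the Discrimination Index
#'
#' Recomputes the full index under random permutations of the group
#' labels (group sizes preserved) and applies the add-one estimator
#' \eqn{p = (1 + \#\{perm \ge obs\}) / (B + 1)}. The decorrelating
#' rotation is label-free (it is fitted on the pooled samples), so the
#' fitted space is reused across permutations; only the discriminant
#' statistics change.
#'
#' @inheritParams discriminationIndex
#' @param nLabelPermutations number of label permutations (default 1000).
#' @return the observed \linkS4class{DiscriminationResult} with
#'   \code{pValue} filled in.
#' @export
discriminationPValue <- function(be, groupA, groupB, space = NULL,
        varianceKept = 0.95, nSubsamples = 200, holdoutFraction = 0.5,
        nLabelPermutations = 1000, seed) {
    stopifnot(nLabelPermutations >= 1)
    if (is.null(space))
        space <- fitDRFSpace(be, groupA, groupB, varianceKept)
    ia <- selectSamples(be, groupA, "groupA")
    ib <- selectSamples(be, groupB, "groupB")
    Y <- projectDRF(space, be[, c(ia, ib)])
    nA <- length(ia); n <- nA + length(ib)
    obs <- discriminationIndex(be, groupA, groupB, space = space,
        nSubsamples = nSubsamples, holdoutFraction = holdoutFraction,
        seed = deriveSeed(seed, 0))
    permIdx <- withSeed(deriveSeed(seed, 1),
        replicate(nLabelPermutations, sample.int(n, nA), simplify = FALSE))
    permIndex <- vapply(seq_len(nLabelPermutations), function(i) {
        pa <- permIdx[[i]]
        acc <- holdoutAccuracies(Y[pa, , drop = FALSE],
                                 Y[-pa, , drop = FALSE],
                                 nSubsamples, holdoutFraction,
                                 deriveSeed(seed, 1 + i))
        max(50, 100 * mean(acc))
    }, numeric(1))
    p <- (1 + sum(permIndex >= obs@indexPercent)) / (nLabelPermutations + 1)
    methods::initialize(obs, pValue = p)
}

cloudFromScores <- function(Y, label, components = c(1L, 2L)) {
    components <- components[components <= ncol(Y)]
    if (!length(components)) components <- 1L
    components <- rep(components, length.out = 2)
    Y2 <- Y[, components, drop = FALSE]
    n <- nrow(Y2)
    degenerate <- n < 2
    sdAxes <- if (degenerate) c(NA_real_, NA_real_) else apply(Y2, 2, sd)
    methods::new("GroupCloud", label = label, mean2d = colMeans(Y2),
        sdAxes = sdAxes, semAxes = sdAxes / sqrt(n), n = as.integer(n),
        components = as.integer(components[1:2]), degenerate = degenerate)
}

#' 2D cloud summary of a group in DRF space
#'
#' Mean and axis-aligned SD / SEM ellipses of one group on two chosen
#' discriminant components (the components are decorrelated, so the
#' ellipses are axis-aligned by construction). The SEM axes are exactly
#' the SD axes divided by sqrt(n). A single-sample group is flagged
#' degenerate with NA dispersion.
#'
#' @param be a \linkS4class{BehaviorExperiment}.
#' @param group a sample selector.
#' @param space a fitted \linkS4class{DRFSpace}.
#' @param displayComponents which discriminant-ordered components to
#'   display (default the two most discriminant).
#' @return a \linkS4class{GroupCloud}.
#' @export
cloudSummary <- function(be, group, space, displayComponents = c(1, 2)) {
    if (any(displayComponents > ncol(space@rotation)))
        stop("requested component beyond retained dimensionality")
    Y <- projectDRF(space, be[, selectSamples(be, group, "group")])
    cloudFromScores(Y, selectorLabel(group), as.integer(displayComponents))
}

#' Recovery Index: treatment rescue along the model-to-control axis
#'
#' Projects every sample of the disease-model, wild-type and test
#' (treated) groups into whitened DRF space, then orthogonally onto the
#' segment joining the model and WT group means, with the scalar
#' coordinate scaled so the model mean sits at exactly 0 and the WT mean
#' at exactly 1. Recovery is 100 x the test group's mean coordinate,
#' clamped to [0, 100]: 0 means the treated group overlaps the untreated
#' model (or beyond), 100 that it overlaps the controls (or beyond).
#'
#' @param be a \linkS4class{BehaviorExperiment}.
#' @param modelGroup,wtGroup,testGroup sample selectors.
#' @param space optional pre-fitted \linkS4class{DRFSpace}; fitted on
#'   model vs WT with \code{varianceKept} when NULL.
#' @param varianceKept used only when fitting internally.
#' @return a \linkS4class{RecoveryResult} with per-sample projections;
#'   \code{pValue} is NA until \code{\link{recoveryPValue}}.
#' @export
recoveryIndex <- function(be, modelGroup, wtGroup, testGroup,
        space = NULL, varianceKept = 0.95) {
    if (is.null(space))
        space <- fitDRFSpace(be, modelGroup, wtGroup, varianceKept)
    proj <- lapply(list(model = modelGroup, wt = wtGroup, test = testGroup),
        function(sel) projectDRF(space, be[, selectSamples(be, sel)]))
    mM <- colMeans(proj$model); mW <- colMeans(proj$wt)
    u <- mW - mM
    uu <- sum(u^2)
    if (uu < 1e-24)
        stop("model and WT group means coincide; recovery axis undefined")
    coord <- lapply(proj, function(Y)
        setNames(as.numeric((Y - rep(mM, each = nrow(Y))) %*% u / uu),
                 rownames(Y)))
    methods::new("RecoveryResult",
        recoveryPercent = 100 * clamp(mean(coord$test), 0, 1),
        pValue = NA_real_, projections = coord,
        segment = list(model_mean = mM, wt_mean = mW),
        groups = c(selectorLabel(modelGroup), selectorLabel(wtGroup),
                   selectorLabel(testGroup)))
}

#' Parametric p-value for the Recovery Index
#'
#' One-sided Welch t-test on the scalar projections, test group vs
#' untreated model group, with the alternative that the test group is
#' shifted toward the wild-type end of the axis (null: no difference).
#'
#' @param result a \linkS4class{RecoveryResult}.
#' @return the result with \code{pValue} filled in.
#' @export
recoveryPValue <- function(result) {
    x <- result@projections$test
    y <- result@projections$model
    if (length(x) < 2 || length(y) < 2)
        stop("need >= 2 samples in test and model groups")
    vx <- var(x); vy <- var(y)
    se2 <- vx / length(x) + vy / length(y)
    p <- if (se2 == 0) {
        if (mean(x) > mean(y)) 0 else 1
    } else {
        t <- (mean(x) - mean(y)) / sqrt(se2)
        df <- se2^2 / ((vx / length(x))^2 / (length(x) - 1) +
                       (vy / length(y))^2 / (length(y) - 1))
        pt(t, df, lower.tail = FALSE)
    }
    methods::initialize(result, pValue = p)
}
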