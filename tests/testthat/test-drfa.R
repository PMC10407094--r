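test_that("fitted space decorrelates the pooled training data", {
    be <- gaussianBE(8, 8, 10, sep = 1, seed = 2)
    sp <- fitDRFSpace(be, "A", "B", varianceKept = 0.95)
    Y <- projectDRF(sp, be, whiten = FALSE)
    C <- cov(Y)
    r <- cov2cor(C)
    expect_lt(max(abs(r[upper.tri(r)])), 1e-8)
    # whitened projection has unit variance per component on the pool
    Yw <- projectDRF(sp, be, whiten = TRUE)
    expect_equal(unname(apply(Yw, 2, var)), rep(1, ncol(Yw)),
                 tolerance = 1e-8)
    # rotation columns orthonormal (validity enforces; check directly)
    expect_equal(crossprod(sp@rotation),
                 diag(ncol(sp@rotation)), tolerance = 1e-10,
                 ignore_attr = TRUE)
})

test_that("retained dimensionality equals the rank of degenerate data", {
    set.seed(4)
    base <- matrix(rnorm(14 * 2), 14, 2)
    X <- cbind(base[, 1], base[, 2], base[, 1] + base[, 2],
               base[, 1] - 2 * base[, 2])
    dimnames(X) <- list(sprintf("s%02d", 1:14), paste0("f", 1:4))
    be <- makeBE(X, rep(c("A", "B"), each = 7))
    sp <- fitDRFSpace(be, "A", "B", varianceKept = 1)
    expect_identical(ncol(sp@rotation), 2L)

    expect_error(fitDRFSpace(makeBE(matrix(1, 8, 3,
        dimnames = list(paste0("s", 1:8), paste0("f", 1:3))),
        rep(c("A", "B"), each = 4)), "A", "B"), "constant")
    expect_error(fitDRFSpace(gaussianBE(2, 5, 3), "A", "B"), ">= 3")
})

test_that("duplicated features collapse into one component, matching eigen", {
    set.seed(9)
    x1 <- rnorm(20); x3 <- rnorm(20)
    X <- cbind(f1 = x1, f2 = x1, f3 = x3)
    rownames(X) <- sprintf("s%02d", 1:20)
    be <- makeBE(X, rep(c("A", "B"), each = 10))
    sp <- fitDRFSpace(be, "A", "B", varianceKept = 1)
    expect_identical(ncol(sp@rotation), 2L)
    # oracle: eigendecomposition of the standardized covariance
    Z <- scale(X)
    eig <- eigen(cov(Z), symmetric = TRUE)
    for (k in seq_len(2)) {
        v <- sp@rotation[, k]
        match1 <- min(max(abs(v - eig$vectors[, 1])),
                      max(abs(v + eig$vectors[, 1])))
        match2 <- min(max(abs(v - eig$vectors[, 2])),
                      max(abs(v + eig$vectors[, 2])))
        expect_lt(min(match1, match2), 1e-8)
    }
    # duplicates carry identical |loadings| on every retained component
    expect_equal(abs(sp@rotation[1, ]), abs(sp@rotation[2, ]),
                 tolerance = 1e-8)
})

test_that("discrimination is near chance for exchangeable groups", {
    set.seed(31)
    idx <- replicate(30, {
        be <- gaussianBE(10, 10, 8, sep = 0, seed = sample.int(1e6, 1))
        discriminationPercent(discriminationIndex(be, "A", "B",
            nSubsamples = 40, seed = 11))
    })
    expect_gte(min(idx), 50)
    expect_lt(mean(idx), 58)
})

test_that("widely separated groups discriminate almost perfectly", {
    be <- gaussianBE(10, 10, 5, sep = 10, seed = 7)
    di <- discriminationIndex(be, "A", "B", nSubsamples = 100, seed = 3)
    expect_gte(discriminationPercent(di), 99)
    expect_identical(di@classifier, "nearest-centroid")
    # bit-reproducible under a fixed seed, including a single subsample
    d1 <- discriminationIndex(be, "A", "B", nSubsamples = 1, seed = 5)
    d2 <- discriminationIndex(be, "A", "B", nSubsamples = 1, seed = 5)
    expect_identical(d1@indexPercent, d2@indexPercent)
    expect_identical(d1@accuracies, d2@accuracies)
})

test_that("label-permutation p sits at the floor for separated groups", {
    be <- gaussianBE(8, 8, 4, sep = 8, seed = 13)
    res <- discriminationPValue(be, "A", "B", nSubsamples = 25,
                                nLabelPermutations = 49, seed = 2)
    expect_identical(pValue(res), 1 / 50)
    expect_gte(discriminationPercent(res), 99)
})

test_that("an observed index of 50 cannot be significant (clamp edge)", {
    found <- FALSE
    for (seed in 1:8) {
        be <- gaussianBE(6, 6, 3, sep = 0, seed = 40 + seed)
        res <- discriminationPValue(be, "A", "B", nSubsamples = 20,
                                    nLabelPermutations = 19, seed = seed)
        if (discriminationPercent(res) == 50) {
            found <- TRUE
            expect_identical(pValue(res), 1)
        }
    }
    expect_true(found)  # a chance-level null replicate must occur
})

test_that("cloud ellipses scale as SD/sqrt(n) and translate with the group", {
    be <- gaussianBE(4, 6, 5, sep = 1, seed = 21)
    sp <- fitDRFSpace(be, "A", "B", varianceKept = 1)
    cl <- cloudSummary(be, "A", sp)
    expect_identical(cl@n, 4L)
    expect_equal(cl@semAxes, cl@sdAxes / 2, tolerance = 1e-12)

    # translating the raw features moves the mean, not the ellipses
    X <- t(SummarizedExperiment::assay(be, "features"))
    X2 <- X; X2[1:4, ] <- X2[1:4, ] + 5
    be2 <- makeBE(X2, rep(c("A2", "B"), c(4, 6)))
    cl2 <- cloudSummary(be2, "A2", sp)
    expect_equal(cl2@sdAxes, cl@sdAxes, tolerance = 1e-9)
    expect_false(isTRUE(all.equal(cl2@mean2d, cl@mean2d)))

    # single-sample group flagged degenerate
    cl1 <- cloudSummary(be, "s01", sp)
    expect_true(cl1@degenerate)
    expect_true(all(is.na(cl1@sdAxes)))
})

test_that("recovery hits the exact endpoints and midpoint", {
    set.seed(6)
    X <- matrix(rnorm(30 * 6), 30, 6,
                dimnames = list(sprintf("s%02d", 1:30), paste0("f", 1:6)))
    X[1:10, ] <- X[1:10, ] + 2      # model shifted away from WT
    grp <- rep(c("model", "WT", "test"), each = 10)
    # test group at the exact midpoint of the two other samples
    X[21:30, ] <- (X[1:10, ] + X[11:20, ]) / 2
    be <- makeBE(X, grp)
    sp <- fitDRFSpace(be, "model", "WT", varianceKept = 1)

    recWT <- recoveryIndex(be, "model", "WT", "WT", space = sp)
    expect_equal(recoveryPercent(recWT), 100, tolerance = 1e-9)
    recHD <- recoveryIndex(be, "model", "WT", "model", space = sp)
    expect_equal(recoveryPercent(recHD), 0, tolerance = 1e-9)
    recMid <- recoveryIndex(be, "model", "WT", "test", space = sp)
    expect_equal(recoveryPercent(recMid), 50, tolerance = 1e-6)

    # model mean maps to 0 and WT mean to 1 exactly
    expect_equal(mean(recMid@projections$model), 0, tolerance = 1e-10)
    expect_equal(mean(recMid@projections$wt), 1, tolerance = 1e-10)
})

test_that("coincident group means leave the recovery axis undefined", {
    set.seed(8)
    X <- matrix(rnorm(12 * 4), 12, 4,
                dimnames = list(sprintf("s%02d", 1:12), paste0("f", 1:4)))
    X[7:12, ] <- X[1:6, ]          # identical point clouds
    be <- makeBE(X, rep(c("model", "WT"), each = 6))
    expect_error(recoveryIndex(be, "model", "WT", "WT"), "coincide")
})

test_that("recovery is invariant under invertible affine maps of raw features", {
    set.seed(19)
    p <- 6
    X <- matrix(rnorm(36 * p), 36, p,
                dimnames = list(sprintf("s%02d", 1:36), paste0("f", 1:p)))
    X[1:12, ] <- X[1:12, ] + 1.5
    X[25:36, ] <- X[25:36, ] +
        matrix(runif(p), 12, p, byrow = TRUE)  # a partially recovered group
    grp <- rep(c("model", "WT", "test"), each = 12)
    be <- makeBE(X, grp)
    r0 <- recoveryPercent(recoveryIndex(be, "model", "WT", "test",
                                        varianceKept = 1))
    A <- matrix(rnorm(p * p), p, p) + diag(p) * 2
    b <- rnorm(p)
    X2 <- sweep(X %*% A, 2, b, "+")
    colnames(X2) <- colnames(X)
    be2 <- makeBE(X2, grp)
    r1 <- recoveryPercent(recoveryIndex(be2, "model", "WT", "test",
                                        varianceKept = 1))
    expect_equal(r0, r1, tolerance = 1e-6)
})

test_that("recovery p-value matches the textbook Welch computation", {
    res <- new("RecoveryResult", recoveryPercent = 50, pValue = NA_real_,
        projections = list(model = c(m1 = 0.1, m2 = -0.2, m3 = 0.1),
                           wt = c(w1 = 1, w2 = 1.1),
                           test = c(t1 = 0.5, t2 = 0.8, t3 = 0.6)),
        segment = list(), groups = c("model", "WT", "test"))
    p <- pValue(recoveryPValue(res))
    oracle <- t.test(c(0.5, 0.8, 0.6), c(0.1, -0.2, 0.1),
                     alternative = "greater")$p.value
    expect_equal(p, oracle, tolerance = 1e-12)

    # exact null: identical projections give p = 0.5 (t = 0)
    resNull <- new("RecoveryResult", recoveryPercent = 0,
        pValue = NA_real_,
        projections = list(model = c(a = 0.1, b = 0.3, c = 0.2),
                           wt = c(w = 1, x = 1.2),
                           test = c(d = 0.1, e = 0.3, f = 0.2)),
        segment = list(), groups = c("model", "WT", "test"))
    expect_gte(pValue(recoveryPValue(resNull)), 0.5)

    # degenerate zero-variance projections with equal means: p = 1
    resFlat <- new("RecoveryResult", recoveryPercent = 0,
        pValue = NA_real_,
        projections = list(model = c(a = 0, b = 0),
                           wt = c(w = 1, x = 1), test = c(d = 0, e = 0)),
        segment = list(), groups = c("model", "WT", "test"))
    expect_identical(pValue(recoveryPValue(resFlat)), 1)
})
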