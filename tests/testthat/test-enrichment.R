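test_that("running curve reproduces the direct loop on a worked instance", {
    r <- drugRanking(setNames(c(3, 2, 1, -1, -2, -3), paste0("f", 1:6)),
                     "d", 10)
    out <- runningEnrichmentScore(r, c("f1", "f4"), weightExponent = 1)
    expect_equal(out$curve$running_es,
                 c(0.75, 0.50, 0.25, 0.50, 0.25, 0.00), tolerance = 1e-12)
    expect_equal(out$es, 0.75, tolerance = 1e-12)
    # same instance, classic KS form, against the loop oracle
    out0 <- runningEnrichmentScore(r, c("f1", "f4"), weightExponent = 0)
    oracle <- bruteForceES(r@score, r@feature %in% c("f1", "f4"), 0)
    expect_equal(out0$es, oracle$es, tolerance = 1e-12)
})

test_that("a set covering the whole ranking climbs monotonically to 1", {
    r <- randomRanking(12, seed = 3)
    out <- runningEnrichmentScore(r, r@feature)
    expect_true(all(diff(out$curve$running_es) > 0))
    expect_equal(max(out$curve$running_es), 1, tolerance = 1e-12)
    expect_equal(out$es, 1, tolerance = 1e-12)
})

test_that("running sum closes at zero and extremum matches the loop oracle", {
    for (seed in 1:40) {
        set.seed(seed)
        n <- sample(5:50, 1)
        r <- randomRanking(n, seed = seed + 100)
        m <- sample.int(min(10, n - 1), 1)
        fs <- sample(r@feature, m)
        w <- sample(c(0, 1), 1)
        out <- runningEnrichmentScore(r, fs, w)
        oracle <- bruteForceES(r@score, r@feature %in% fs, w)
        expect_equal(out$es, oracle$es, tolerance = 1e-12)
        expect_lt(abs(out$curve$running_es[n]), 1e-9)
        expect_true(all(abs(out$curve$running_es) <= 1 + 1e-12))
        # theoretical maximum dominates the realised walk pointwise
        expect_true(all(out$curve$theoretical_max >=
                        out$curve$running_es - 1e-12))
    }
})

test_that("set resolution errors are informative", {
    r <- randomRanking(8, seed = 5)
    expect_error(runningEnrichmentScore(r, character(0)), "empty")
    expect_error(runningEnrichmentScore(r, c("f001", "nope")), "nope")
})

test_that("perfect reverser and perfect mimic score at opposite extremes", {
    set.seed(11)
    disease <- setNames(rnorm(40), sprintf("f%03d", 1:40))
    sig <- makeSignature(
        increased = sort(disease[disease > 0], decreasing = TRUE)[1:5],
        decreased = {
            d <- disease[disease < 0]
            d[order(abs(d), decreasing = TRUE)][1:5]
        })
    reverser <- drugRanking(-disease, "rev", 10)
    mimic <- drugRanking(disease, "mim", 10)
    resR <- enrichmentReversal(reverser, sig)
    resM <- enrichmentReversal(mimic, sig)
    expect_lt(resR@esIncreased, 0)
    expect_gt(resR@esDecreased, 0)
    expect_gt(reversalScore(resR), 0)
    expect_lt(reversalScore(resM), 0)
    # exact mirror antisymmetry between the two
    expect_equal(resR@esIncreased, -resM@esIncreased, tolerance = 1e-12)
    expect_equal(resR@esDecreased, -resM@esDecreased, tolerance = 1e-12)
    expect_equal(reversalScore(resR), -reversalScore(resM),
                 tolerance = 1e-12)
})

test_that("negating all drug scores negates the reversal score", {
    for (seed in 1:10) {
        set.seed(seed)
        scores <- setNames(rnorm(30), sprintf("f%03d", 1:30))
        nm <- sample(names(scores), 4)
        sig <- makeSignature(increased = setNames(c(3, 2), nm[1:2]),
                             decreased = setNames(c(-3, -2), nm[3:4]))
        a <- enrichmentReversal(drugRanking(scores, "d", 1), sig,
                                sameSignZero = FALSE)
        b <- enrichmentReversal(drugRanking(-scores, "d", 1), sig,
                                sameSignZero = FALSE)
        expect_equal(a@esIncreased, -b@esIncreased, tolerance = 1e-12)
        expect_equal(a@esDecreased, -b@esDecreased, tolerance = 1e-12)
        expect_equal(reversalScore(a), -reversalScore(b),
                     tolerance = 1e-12)
    }
})

test_that("same-sign extrema yield a zero reversal score under the rule", {
    # both sets sit at the top of the profile: enrichment in the same
    # direction is not reversal
    r <- drugRanking(setNames(c(3, 2, 1, -1, -2, -3), paste0("f", 1:6)),
                     "d", 10)
    sig <- makeSignature(increased = c(f1 = 4), decreased = c(f2 = -4))
    res <- enrichmentReversal(r, sig)
    expect_gt(res@esIncreased, 0)
    expect_gt(res@esDecreased, 0)
    expect_identical(reversalScore(res), 0)
    resOff <- enrichmentReversal(r, sig, sameSignZero = FALSE)
    expect_equal(reversalScore(resOff),
                 (resOff@esDecreased - resOff@esIncreased) / 2,
                 tolerance = 1e-12)
})

test_that("signature features missing from a ranking are dropped with warning", {
    r <- randomRanking(10, seed = 2)
    sig <- makeSignature(
        increased = setNames(c(2, 1.5), c(r@feature[1], "ghost")),
        decreased = setNames(-2, r@feature[10]))
    expect_warning(res <- enrichmentReversal(r, sig), "ghost|dropped")
    expect_s4_class(res, "EnrichmentResult")
})

test_that("permutation p honours the add-one floor and estimator bounds", {
    set.seed(21)
    disease <- setNames(rnorm(50), sprintf("f%03d", 1:50))
    sig <- makeSignature(
        increased = sort(disease, decreasing = TRUE)[1:4],
        decreased = sort(disease)[1:4] )
    reverser <- drugRanking(-disease, "rev", 10)
    res <- permutationPValue(reverser, sig, nPermutations = 99, seed = 4)
    expect_gte(pValue(res), 1 / 100)
    expect_identical(pValue(res), 1 / 100)  # exceeds every permuted draw
    expect_identical(res@nPermutations, 99L)

    # boundary: sets jointly exhausting the ranking still resample
    r <- randomRanking(12, seed = 9)
    sigFull <- makeSignature(
        increased = setNames(seq(6, 1), r@feature[1:6]),
        decreased = setNames(-(6:1), r@feature[7:12]))
    pFull <- pValue(permutationPValue(r, sigFull, nPermutations = 49,
                                      seed = 2))
    expect_gte(pFull, 1 / 50)
    expect_lte(pFull, 1)
})

test_that("Monte-Carlo permutation p agrees with exhaustive enumeration", {
    r <- randomRanking(6, seed = 13)
    sig <- makeSignature(increased = setNames(2, r@feature[2]),
                         decreased = setNames(-2, r@feature[5]))
    obs <- enrichmentReversal(r, sig)
    null <- enumerateSingletonNull(r)
    # the enumeration is the complete null, so the reference is the
    # exact exceedance probability (tie tolerance bridges the oracle's
    # different accumulation order); the add-one Monte-Carlo estimator
    # converges to it
    pExact <- mean(null >= reversalScore(obs) - 1e-9)
    B <- 4000
    res <- permutationPValue(r, sig, nPermutations = B, seed = 31)
    se <- sqrt(pExact * (1 - pExact) / B)
    expect_lt(abs(pValue(res) - pExact), 3 * se + 1 / B)
})
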