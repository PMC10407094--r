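test_that("singleton library gets rank 1 and q equal to p", {
    r <- randomRanking(20, seed = 1)
    sig <- makeSignature(increased = setNames(c(2, 1), r@feature[19:20]),
                         decreased = setNames(c(-2, -1), r@feature[1:2]))
    tab <- screenLibrary(list(r), sig, nPermutations = 99, seed = 7,
                         stratum = "F")
    expect_identical(nrow(tab), 1L)
    expect_identical(tab$rank, 1L)
    expect_identical(tab$fdr_q, tab$p_value)
    expect_identical(tab$stratum, "F")
})

test_that("screens are deterministic given the seed and reject duplicates", {
    lib <- lapply(1:4, function(i) randomRanking(15, seed = i,
                                                 drugId = paste0("d", i)))
    sig <- makeSignature(
        increased = setNames(c(2, 1), lib[[1]]@feature[1:2]),
        decreased = setNames(c(-2, -1), lib[[1]]@feature[14:15]))
    t1 <- screenLibrary(lib, sig, nPermutations = 50, seed = 5)
    t2 <- screenLibrary(lib, sig, nPermutations = 50, seed = 5)
    expect_identical(t1, t2)
    expect_identical(t1$rank, seq_len(4L))
    expect_true(!is.unsorted(-t1$reversal_score))

    libDup <- c(lib, lib[1])
    expect_error(screenLibrary(libDup, sig, nPermutations = 10, seed = 1),
                 "duplicate")
})

test_that("rank ties break by p-value then lexicographic drug id", {
    # two drugs with identical profiles: identical reversal scores;
    # identical derived permutation nulls would tie, so force distinct p
    # by running the screen and checking the documented ordering holds
    s <- setNames(c(3, 2, 1, -1, -2, -3), paste0("f", 1:6))
    lib <- list(drugRanking(s, "bbb", 10), drugRanking(s, "aaa", 10))
    sig <- makeSignature(increased = c(f6 = 2), decreased = c(f1 = -2))
    tab <- screenLibrary(lib, sig, nPermutations = 200, seed = 3)
    expect_equal(tab$reversal_score[1], tab$reversal_score[2])
    ord <- order(-tab$reversal_score, tab$p_value, tab$drug_id)
    expect_identical(ord, 1:2)
    if (tab$p_value[1] == tab$p_value[2])
        expect_identical(tab$drug_id, c("aaa", "bbb"))
})

test_that("a planted exact reverser tops the screen of a null library", {
    cfg <- simulationConfig(nFeatures = 100, nAffected = 20,
        nPerGroup = 12, librarySpec = defaultLibrarySpec(nNull = 10,
        doses = 30), seed = 17)
    truth <- simulateTruth(cfg)
    cohort <- simulateCohort(cfg, truth)
    sig <- buildDiseaseSignature(
        featureTScores(cohort$experiment, "model", "WT"), kPerTail = 15)
    lib <- simulateLibrary(cfg, truth)
    tab <- screenLibrary(lib$rankings, sig, nPermutations = 99, seed = 23)
    expect_identical(tab$drug_id[1], "reverser-1")
    expect_lt(tab$p_value[1], 0.05)
    mim <- tab[tab$drug_id == "mimic-1", ]
    expect_true(all(mim$reversal_score < 0))
})

test_that("consistency filter keeps only drugs predicted in every stratum", {
    m <- screenFixture(c("A", "B", "C"), 10, p = c(0.01, 0.20, 0.01),
                       score = c(0.8, 0.5, 0.6), stratum = "M")
    f <- screenFixture(c("A", "B", "C"), 10, p = c(0.02, 0.01, 0.30),
                       score = c(0.7, 0.6, 0.5), stratum = "F")
    kept <- consistencyFilter(list(M = m, F = f), alpha = 0.05)
    # A significant in both; B only in F; C only in M
    expect_identical(kept$drug_id, "A")
    expect_identical(names(kept)[3:6],
                     c("reversal_M", "p_M", "reversal_F", "p_F"))

    # vacuous threshold keeps every shared pair with positive scores
    keptAll <- consistencyFilter(list(M = m, F = f), alpha = 1)
    expect_setequal(keptAll$drug_id, c("A", "B", "C"))
})

test_that("consistency filter drops unshared drugs with a warning, needs 2 strata", {
    m <- screenFixture(c("A", "B"), 10, p = c(0.01, 0.01), score = c(0.8, 0.7),
                       stratum = "M")
    f <- screenFixture("A", 10, p = 0.01, score = 0.6, stratum = "F")
    expect_warning(kept <- consistencyFilter(list(M = m, F = f)), "B@10")
    expect_identical(kept$drug_id, "A")
    expect_error(consistencyFilter(list(M = m)), "2 strata")

    # negative or zero reversal never passes, whatever the p-value
    neg <- screenFixture("A", 10, p = 0.001, score = -0.5, stratum = "F")
    kept2 <- suppressWarnings(consistencyFilter(list(M = m, F = neg)))
    expect_identical(nrow(kept2), 0L)
})

test_that("screen tables round-trip through TSV with stable columns", {
    lib <- lapply(1:3, function(i) randomRanking(10, seed = i,
                                                 drugId = paste0("d", i)))
    sig <- makeSignature(
        increased = setNames(2, lib[[1]]@feature[1]),
        decreased = setNames(-2, lib[[1]]@feature[10]))
    tab <- screenLibrary(lib, sig, nPermutations = 20, seed = 2,
                         stratum = "F")
    path <- withr::local_tempfile(fileext = ".tsv")
    writeScreenTable(tab, path)
    back <- readScreenTable(path)
    expect_identical(back$drug_id, tab$drug_id)
    expect_equal(back$reversal_score, tab$reversal_score, tolerance = 1e-8)
    expect_identical(names(back), names(tab))
})
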