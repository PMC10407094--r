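# Shared fixtures and independent oracles for the suite. The oracles are
# deliberately plain loop/enumeration implementations kept separate from
# the package's vectorised code paths.

# samples x features matrix -> BehaviorExperiment with a group column
makeBE <- function(values, groups, ...) {
    BehaviorExperiment(values, data.frame(group = groups, ...))
}

# Two-group Gaussian cohort: nA + nB samples, p iid features, the first
# group shifted by `sep` on every axis.
gaussianBE <- function(nA, nB, p, sep = 0, seed = 1) {
    set.seed(seed)
    X <- matrix(rnorm((nA + nB) * p), nA + nB, p,
                dimnames = list(sprintf("s%02d", seq_len(nA + nB)),
                                sprintf("f%02d", seq_len(p))))
    X[seq_len(nA), ] <- X[seq_len(nA), ] + sep
    makeBE(X, rep(c("A", "B"), c(nA, nB)))
}

# Independent running-sum oracle: explicit position-by-position loop.
bruteForceES <- function(scores, isHit, exponent) {
    n <- length(scores)
    m <- sum(isHit)
    sumw <- 0
    for (i in seq_len(n))
        if (isHit[i]) sumw <- sumw + abs(scores[i])^exponent
    run <- 0
    peak <- -Inf
    trough <- Inf
    endval <- NA_real_
    for (i in seq_len(n)) {
        if (isHit[i]) {
            run <- run + if (sumw > 0) abs(scores[i])^exponent / sumw else 1 / m
        } else {
            run <- run - 1 / (n - m)
        }
        if (run > peak) peak <- run
        if (run < trough) trough <- run
        endval <- run
    }
    # same tie convention as the package: equal-magnitude extrema
    # resolve to the positive peak
    best <- if (peak >= -trough - 1e-9) peak else trough
    list(es = best, end = endval)
}

# Oracle reversal score for given hit sets (same-sign rule applied).
bruteForceReversal <- function(scores, hitUp, hitDn, exponent) {
    eu <- bruteForceES(scores, hitUp, exponent)$es
    ed <- bruteForceES(scores, hitDn, exponent)$es
    if (eu * ed > 0) 0 else (ed - eu) / 2
}

# Exhaustive null of the reversal score for singleton increased /
# decreased sets: all ordered disjoint pairs (i, j), i != j.
enumerateSingletonNull <- function(ranking, exponent = 1) {
    scores <- ranking@score
    n <- length(scores)
    out <- numeric(0)
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        hitU <- seq_len(n) == i
        hitD <- seq_len(n) == j
        out <- c(out, bruteForceReversal(scores, hitU, hitD, exponent))
    }
    out
}

# Minimal valid signature from explicit named sets (bypasses selection).
makeSignature <- function(increased, decreased) {
    new("DiseaseSignature", increased = increased, decreased = decreased,
        selection = list(k_per_tail = length(increased), min_abs_t = 0))
}

# A ranked profile over n features with continuous random scores.
randomRanking <- function(n, seed, drugId = "drug", dose = 10) {
    set.seed(seed)
    drugRanking(setNames(rnorm(n), sprintf("f%03d", seq_len(n))),
                drugId, dose)
}

# Hand-built screen table row set for consistency-filter fixtures.
screenFixture <- function(drug, dose, p, score, stratum = "F") {
    data.frame(drug_id = drug, dose = dose, stratum = stratum,
               es_increased = -score, es_decreased = score,
               reversal_score = score, p_value = p,
               fdr_q = p, rank = rank(-score, ties.method = "first"),
               stringsAsFactors = FALSE)
}
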