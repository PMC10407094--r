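# Synthetic behavioral cohorts and drug libraries with planted ground
# truth. Features follow a correlated Gaussian model (shared low-rank
# factors plus independent noise); the disease adds a signed effect on a
# known feature subset; library drugs are planted reversers, mimics,
# partial reversers or nulls whose effect scales monotonically with dose.

#' Default synthetic drug library layout
#'
#' One exact reverser, one mimic, one partial reverser and \code{nNull}
#' inactive drugs, each at the given doses (mg/kg). The highest dose
#' carries the full archetype strength; lower doses scale it down
#' proportionally.
#'
#' @param nNull number of inactive drugs (default 47, for a round
#'   50-drug screen).
#' @param doses numeric dose levels per drug.
#' @return data.frame with columns \code{drug_id}, \code{dose},
#'   \code{archetype}, \code{strength}.
#' @export
defaultLibrarySpec <- function(nNull = 47, doses = c(10, 30)) {
    drugs <- data.frame(
        drug_id = c("reverser-1", "mimic-1", "partial-1",
                    sprintf("null-%02d", seq_len(nNull))),
        archetype = c("reverser", "mimic", "partial", rep("null", nNull)),
        strength = c(1, 1, 0.5, rep(0, nNull)),
        stringsAsFactors = FALSE)
    out <- merge(drugs, data.frame(dose = doses), by = NULL)
    out[order(out$drug_id, out$dose),
        c("drug_id", "dose", "archetype", "strength")]
}

#' Build a simulation configuration
#'
#' Defaults describe a mid-sized phenotyping cohort: 200 correlated
#' features of which 40 carry the disease effect at 1.5 total-SD units,
#' 5 shared latent factors contributing 0.6 variance against unit
#' independent noise, 15 animals per group, and the 50-drug two-dose
#' library of \code{\link{defaultLibrarySpec}}.
#'
#' @param nFeatures,nAffected feature counts (affected <= total).
#' @param effectSize disease effect on each affected feature, in units
#'   of the feature's total SD.
#' @param nFactors,factorStrength latent factor count and the variance
#'   each feature receives from the factors.
#' @param nPerGroup animals per experimental group.
#' @param noiseSd SD of the independent noise component.
#' @param librarySpec drug library layout (see
#'   \code{\link{defaultLibrarySpec}}).
#' @param seed top-level integer seed; all child streams derive from it.
#' @return a \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(nFeatures = 200, nAffected = 40,
        effectSize = 1.5, nFactors = 5, factorStrength = 0.6,
        nPerGroup = 15, noiseSd = 1,
        librarySpec = defaultLibrarySpec(), seed = 1) {
    methods::new("SimulationConfig",
        nFeatures = as.integer(nFeatures), nAffected = as.integer(nAffected),
        effectSize = effectSize, nFactors = as.integer(nFactors),
        factorStrength = factorStrength, nPerGroup = as.integer(nPerGroup),
        noiseSd = noiseSd, librarySpec = librarySpec,
        seed = as.integer(seed))
}

#' Draw the planted ground truth for a configuration
#'
#' Samples the shared factor loadings, the affected feature subset and
#' the signed per-feature disease effects. The same truth object is
#' passed to every cohort and library drawn under the configuration so
#' that strata share the disease phenotype and correlation structure.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with \code{featureNames}, \code{loadings} (features x
#'   factors), \code{affected} (feature names), \code{effects} (named
#'   signed effect vector over all features, zero off the affected set),
#'   \code{totalSd} (the model's per-feature SD).
#' @export
simulateTruth <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    withSeed(config@seed, {
        p <- config@nFeatures
        q <- config@nFactors
        features <- sprintf("feat_%03d", seq_len(p))
        L <- matrix(rnorm(p * q, sd = sqrt(config@factorStrength / q)),
                    p, q, dimnames = list(features, NULL))
        totalSd <- sqrt(config@factorStrength + config@noiseSd^2)
        affected <- sort(sample(features, config@nAffected))
        effects <- setNames(numeric(p), features)
        effects[affected] <- config@effectSize * totalSd *
            sample(c(-1, 1), config@nAffected, replace = TRUE)
        list(featureNames = features, loadings = L, affected = affected,
             effects = effects, totalSd = totalSd)
    })
}

# n samples from the factor-noise model, before any group effect.
simBaseline <- function(n, truth, noiseSd, prefix) {
    p <- nrow(truth$loadings); q <- ncol(truth$loadings)
    X <- matrix(rnorm(n * q), n, q) %*% t(truth$loadings) +
        matrix(rnorm(n * p, sd = noiseSd), n, p)
    dimnames(X) <- list(sprintf("%s_%02d", prefix, seq_len(n)),
                        truth$featureNames)
    X
}

#' Generate a synthetic two-group cohort (plus optional treated group)
#'
#' Wild-type samples follow the correlated factor-noise model; disease
#' model samples add the planted signed effect on the affected features.
#' When \code{rescueStrength} is given, a third group
#' (\code{"model_treated"}) carries the disease effect attenuated by
#' that fraction, emulating a partially rescued treated cohort.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param truth output of \code{\link{simulateTruth}}; drawn from
#'   \code{config} when NULL.
#' @param seed sampling seed for this cohort (defaults to the config
#'   seed); strata should pass distinct derived seeds.
#' @param sex,ageMonths metadata recorded for every sample.
#' @param rescueStrength optional fraction in [0, 1]; 1 = full rescue.
#' @return list with \code{experiment} (a
#'   \linkS4class{BehaviorExperiment} with groups \code{"model"},
#'   \code{"WT"} and optionally \code{"model_treated"}) and \code{truth}.
#' @export
simulateCohort <- function(config, truth = NULL, seed = config@seed,
        sex = "F", ageMonths = 6, rescueStrength = NULL) {
    stopifnot(is(config, "SimulationConfig"))
    if (is.null(truth)) truth <- simulateTruth(config)
    n <- config@nPerGroup
    X <- withSeed(seed, {
        wt <- simBaseline(n, truth, config@noiseSd, "WT")
        md <- simBaseline(n, truth, config@noiseSd, "model")
        md <- md + rep(truth$effects, each = n)
        out <- rbind(md, wt)
        if (!is.null(rescueStrength)) {
            stopifnot(rescueStrength >= 0, rescueStrength <= 1)
            tr <- simBaseline(n, truth, config@noiseSd, "treated")
            tr <- tr + rep((1 - rescueStrength) * truth$effects, each = n)
            out <- rbind(out, tr)
        }
        out
    })
    grp <- rep(c("model", "WT", "model_treated"),
               c(n, n, nrow(X) - 2 * n))
    meta <- data.frame(group = grp, sex = sex, age_months = ageMonths,
        treatment = ifelse(grp == "model_treated", "drug", "vehicle"),
        stringsAsFactors = FALSE)
    list(experiment = BehaviorExperiment(X, meta), truth = truth)
}

#' Generate a synthetic drug library as ranked profiles
#'
#' Draws one treated wild-type group per drug-dose plus a single shared
#' vehicle group (mirroring a single-vehicle screening design), applies
#' the archetype effect, and converts each drug-vs-vehicle Welch
#' contrast into a \linkS4class{DrugRanking}. Archetypes: a
#' \emph{reverser} applies \eqn{-s \times} the disease effect, a
#' \emph{mimic} \eqn{+s \times}, a \emph{null} nothing, and a
#' \emph{partial} reverses a random fraction \code{strength} of the
#' affected features; in every case the dose scales the effect by
#' \code{dose / max(dose)} within the drug.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param truth output of \code{\link{simulateTruth}}.
#' @param seed sampling seed for the library (default derived from the
#'   config seed).
#' @return list with \code{rankings} (list of
#'   \linkS4class{DrugRanking}), \code{drugEffects} (true per-drug-dose
#'   effect vectors) and \code{spec} (the library layout used).
#' @export
simulateLibrary <- function(config, truth = NULL,
        seed = deriveSeed(config@seed, 9001)) {
    stopifnot(is(config, "SimulationConfig"))
    if (is.null(truth)) truth <- simulateTruth(config)
    ls <- config@librarySpec
    n <- config@nPerGroup
    withSeed(seed, {
        veh <- simBaseline(n, truth, config@noiseSd, "veh")
        maxDose <- tapply(ls$dose, ls$drug_id, max)
        rankings <- vector("list", nrow(ls))
        drugEffects <- vector("list", nrow(ls))
        for (i in seq_len(nrow(ls))) {
            s <- ls$strength[i] * ls$dose[i] / maxDose[[ls$drug_id[i]]]
            eff <- setNames(numeric(config@nFeatures), truth$featureNames)
            if (ls$archetype[i] == "reverser") {
                eff <- -s * truth$effects
            } else if (ls$archetype[i] == "mimic") {
                eff <- s * truth$effects
            } else if (ls$archetype[i] == "partial") {
                kRev <- round(ls$strength[i] * length(truth$affected))
                sub <- sample(truth$affected, kRev)
                eff[sub] <- -(ls$dose[i] / maxDose[[ls$drug_id[i]]]) *
                    truth$effects[sub]
            }
            trt <- simBaseline(n, truth, config@noiseSd,
                               paste0(ls$drug_id[i], "_", ls$dose[i]))
            trt <- trt + rep(eff, each = n)
            t <- welchStatistic(t(trt), t(veh))
            rankings[[i]] <- drugRanking(
                setNames(t$t, truth$featureNames),
                ls$drug_id[i], ls$dose[i])
            drugEffects[[i]] <- eff
        }
        names(rankings) <- names(drugEffects) <-
            paste(ls$drug_id, ls$dose, sep = "@")
        list(rankings = rankings, drugEffects = drugEffects, spec = ls)
    })
}
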