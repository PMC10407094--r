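# Umbrella pipeline: signature -> per-stratum screen -> consistency
# filter -> optional DRFA validation, driven by one config and one seed.

#' Read a pipeline run configuration
#'
#' YAML or JSON (by extension). Top-level keys: \code{seed} (mandatory);
#' either \code{simulate} (a block of \code{\link{simulationConfig}}
#' parameters plus optional \code{rescue_strength}) or \code{data}
#' (paths: \code{cohorts} named by stratum, \code{library} or
#' \code{libraries} named by stratum); \code{strata} (labels, default
#' \code{c("F", "M")}); \code{groups} (\code{model}, \code{wt},
#' \code{test} labels); optional \code{signature}, \code{screen},
#' \code{consistency}, \code{drfa} blocks overriding module defaults.
#'
#' @param path config file path.
#' @return validated config list.
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
        jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    validateRunConfig(cfg)
}

#' @rdname readRunConfig
#' @param cfg a config list built in code rather than read from file.
#' @export
validateRunConfig <- function(cfg) {
    if (is.null(cfg$seed)) stop("config: 'seed' is mandatory")
    if (is.null(cfg$simulate) && is.null(cfg$data))
        stop("config: provide either a 'simulate' block or a 'data' block")
    cfg$strata <- cfg$strata %||% c("F", "M")
    cfg$groups <- modifyList(list(model = "model", wt = "WT",
                                  test = "model_treated"),
                             as.list(cfg$groups))
    cfg$signature <- modifyList(list(k_per_tail = 20, min_abs_t = 0),
                                as.list(cfg$signature))
    cfg$screen <- modifyList(list(weight_exponent = 1,
                                  n_permutations = 1000,
                                  same_sign_zero = TRUE),
                             as.list(cfg$screen))
    cfg$consistency <- modifyList(list(alpha = 0.05, by = "p"),
                                  as.list(cfg$consistency))
    cfg$drfa <- modifyList(list(enabled = TRUE, variance_kept = 0.95,
                                n_subsamples = 200, holdout_fraction = 0.5,
                                n_label_permutations = 0),
                           as.list(cfg$drfa))
    if (!is.null(cfg$data)) {
        for (s in cfg$strata)
            if (is.null(cfg$data$cohorts[[s]]))
                stop("config: data.cohorts missing path for stratum '", s, "'")
        paths <- unlist(c(cfg$data$cohorts, cfg$data$library,
                          cfg$data$libraries))
        bad <- paths[!file.exists(paths)]
        if (length(bad)) stop("config: input file(s) not found: ",
                              paste(bad, collapse = ", "))
    }
    cfg
}

stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

#' Run the full screening pipeline
#'
#' Executes, per stratum: cohort acquisition (simulated or read from
#' file), disease signature extraction, library screen; then the
#' cross-stratum consistency filter; and optionally DRFA validation
#' (discrimination of model vs WT, recovery of the designated test
#' group) on each stratum's cohort. All stochastic steps receive seeds
#' derived from the config seed, so two runs with the same config
#' produce byte-identical output files.
#'
#' @param cfg config list from \code{\link{readRunConfig}} /
#'   \code{\link{validateRunConfig}}.
#' @param outDir output directory (created if needed); per-stratum
#'   signature JSONs and screen TSVs, \code{consistency.tsv}, optional
#'   \code{drfa.json} and a plain-text \code{summary.txt} are written.
#' @return invisible list with \code{signatures}, \code{screens},
#'   \code{consistent}, \code{drfa} and \code{files}.
#' @export
runPipeline <- function(cfg, outDir) {
    cfg <- validateRunConfig(cfg)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    g <- cfg$groups
    simBlock <- cfg$simulate
    truth <- NULL
    simCfg <- NULL
    if (!is.null(simBlock)) {
        simCfg <- stage("simulate", simulationConfig(
            nFeatures = simBlock$n_features %||% 200,
            nAffected = simBlock$n_affected %||% 40,
            effectSize = simBlock$effect_size %||% 1.5,
            nFactors = simBlock$n_factors %||% 5,
            factorStrength = simBlock$factor_strength %||% 0.6,
            nPerGroup = simBlock$n_per_group %||% 15,
            noiseSd = simBlock$noise_sd %||% 1,
            seed = cfg$seed))
        truth <- simulateTruth(simCfg)
    }
    signatures <- list(); screens <- list(); drfaOut <- list()
    files <- character()
    for (si in seq_along(cfg$strata)) {
        s <- cfg$strata[[si]]
        cohort <- stage(paste0("cohort[", s, "]"), {
            if (!is.null(simCfg))
                simulateCohort(simCfg, truth,
                    seed = deriveSeed(cfg$seed, 100 + si), sex = s,
                    rescueStrength = simBlock$rescue_strength %||% 0.6
                    )$experiment
            else readFeatureMatrix(cfg$data$cohorts[[s]])
        })
        profile <- stage(paste0("signature[", s, "]"),
            featureTScores(cohort, g$model, g$wt))
        sig <- stage(paste0("signature[", s, "]"),
            buildDiseaseSignature(profile,
                kPerTail = cfg$signature$k_per_tail,
                minAbsT = cfg$signature$min_abs_t))
        sigPath <- file.path(outDir, paste0("signature_", s, ".json"))
        writeSignature(sig, sigPath)
        library_ <- stage(paste0("library[", s, "]"), {
            if (!is.null(simCfg))
                simulateLibrary(simCfg, truth,
                    seed = deriveSeed(cfg$seed, 200 + si))$rankings
            else {
                path <- cfg$data$libraries[[s]] %||% cfg$data$library
                readDrugLibrary(path)
            }
        })
        screen <- stage(paste0("screen[", s, "]"),
            screenLibrary(library_, sig,
                weightExponent = cfg$screen$weight_exponent,
                nPermutations = cfg$screen$n_permutations,
                seed = deriveSeed(cfg$seed, 300 + si), stratum = s,
                sameSignZero = cfg$screen$same_sign_zero))
        scrPath <- file.path(outDir, paste0("screen_", s, ".tsv"))
        writeScreenTable(screen, scrPath)
        signatures[[s]] <- sig; screens[[s]] <- screen
        files <- c(files, sigPath, scrPath)
        if (isTRUE(cfg$drfa$enabled)) {
            drfaOut[[s]] <- stage(paste0("drfa[", s, "]"), {
                di <- if (cfg$drfa$n_label_permutations > 0)
                    discriminationPValue(cohort, g$model, g$wt,
                        varianceKept = cfg$drfa$variance_kept,
                        nSubsamples = cfg$drfa$n_subsamples,
                        holdoutFraction = cfg$drfa$holdout_fraction,
                        nLabelPermutations = cfg$drfa$n_label_permutations,
                        seed = deriveSeed(cfg$seed, 400 + si))
                else discriminationIndex(cohort, g$model, g$wt,
                        varianceKept = cfg$drfa$variance_kept,
                        nSubsamples = cfg$drfa$n_subsamples,
                        holdoutFraction = cfg$drfa$holdout_fraction,
                        seed = deriveSeed(cfg$seed, 400 + si))
                rec <- if (g$test %in% sampleGroups(cohort))
                    recoveryPValue(recoveryIndex(cohort, g$model, g$wt,
                        g$test, varianceKept = cfg$drfa$variance_kept))
                else NULL
                list(discrimination = di, recovery = rec)
            })
        }
    }
    consistent <- stage("consistency",
        if (length(screens) >= 2)
            consistencyFilter(screens, alpha = cfg$consistency$alpha,
                              by = cfg$consistency$by)
        else screens[[1]][screens[[1]]$p_value <= cfg$consistency$alpha &
                          screens[[1]]$reversal_score > 0,
                          c("drug_id", "dose")])
    conPath <- file.path(outDir, "consistency.tsv")
    write.table(format(consistent, digits = 10, trim = TRUE,
                       scientific = FALSE),
                conPath, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, conPath)
    if (length(drfaOut)) {
        drfaPath <- file.path(outDir, "drfa.json")
        jsonlite::write_json(lapply(drfaOut, function(d) list(
            discrimination_index_percent = d$discrimination@indexPercent,
            discrimination_p = d$discrimination@pValue,
            n_subsamples = d$discrimination@nSubsamples,
            recovery_percent = if (is.null(d$recovery)) NULL
                               else d$recovery@recoveryPercent,
            recovery_p = if (is.null(d$recovery)) NULL
                         else d$recovery@pValue)),
            drfaPath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
        files <- c(files, drfaPath)
    }
    sumPath <- file.path(outDir, "summary.txt")
    writeLines(c(
        sprintf("strata: %s", paste(cfg$strata, collapse = ", ")),
        sprintf("seed: %d", as.integer(cfg$seed)),
        vapply(names(screens), function(s) sprintf(
            "stratum %s: %d drug-dose rows screened; top hit %s @ %g (reversal %.4f, p %.4g)",
            s, nrow(screens[[s]]), screens[[s]]$drug_id[1],
            screens[[s]]$dose[1], screens[[s]]$reversal_score[1],
            screens[[s]]$p_value[1]), character(1)),
        sprintf("consistent reversers (alpha = %g, by %s): %d",
                cfg$consistency$alpha, cfg$consistency$by,
                nrow(consistent)),
        if (nrow(consistent))
            paste(" ", consistent$drug_id, "@", consistent$dose)
        ), sumPath)
    files <- c(files, sumPath)
    invisible(list(signatures = signatures, screens = screens,
                   consistent = consistent, drfa = drfaOut,
                   files = files))
}
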