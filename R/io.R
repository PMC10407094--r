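# JSON / TSV serialization of profiles, signatures and library rankings.

#' Serialize a disease signature to JSON (and back)
#'
#' The JSON carries both ordered sets with their t scores and the full
#' selection record, so a signature file is self-describing and
#' round-trips losslessly.
#'
#' @param signature a \linkS4class{DiseaseSignature}.
#' @param path JSON file path.
#' @return \code{path} invisibly; \code{readSignature} returns the
#'   reconstructed \linkS4class{DiseaseSignature}.
#' @export
writeSignature <- function(signature, path) {
    obj <- list(
        increased = list(feature = names(signature@increased),
                         t = unname(signature@increased)),
        decreased = list(feature = names(signature@decreased),
                         t = unname(signature@decreased)),
        selection = signature@selection)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

#' @rdname writeSignature
#' @export
readSignature <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    methods::new("DiseaseSignature",
        increased = setNames(as.numeric(obj$increased$t),
                             as.character(obj$increased$feature)),
        decreased = setNames(as.numeric(obj$decreased$t),
                             as.character(obj$decreased$feature)),
        selection = as.list(obj$selection))
}

#' Serialize a contrast profile to JSON (and back)
#'
#' @param profile a \linkS4class{ContrastProfile}.
#' @param path JSON file path.
#' @return \code{path} invisibly; \code{readContrastProfile} returns the
#'   reconstructed object.
#' @export
writeContrastProfile <- function(profile, path) {
    obj <- list(feature = profile@feature, t = profile@t,
                zero_variance = profile@zeroVariance,
                group_a = profile@groupA, group_b = profile@groupB,
                n_a = profile@nA, n_b = profile@nB)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

#' @rdname writeContrastProfile
#' @export
readContrastProfile <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    methods::new("ContrastProfile",
        feature = as.character(obj$feature), t = as.numeric(obj$t),
        zeroVariance = as.logical(obj$zero_variance),
        groupA = obj$group_a, groupB = obj$group_b,
        nA = as.integer(obj$n_a), nB = as.integer(obj$n_b))
}

#' Read / write a drug library as one long delimited table
#'
#' The long format has columns \code{drug_id}, \code{dose},
#' \code{feature}, \code{t_score}; each (drug_id, dose) block becomes
#' one \linkS4class{DrugRanking} (rows are re-sorted by score, stable in
#' file order on ties).
#'
#' @param path TSV (or CSV by extension) file path.
#' @return named list of \linkS4class{DrugRanking} objects.
#' @export
readDrugLibrary <- function(path) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
    need <- c("drug_id", "dose", "feature", "t_score")
    if (!all(need %in% names(df)))
        stop("library table needs columns: ", paste(need, collapse = ", "))
    key <- paste(df$drug_id, df$dose, sep = "@")
    out <- lapply(split(seq_len(nrow(df)), key), function(i)
        drugRanking(setNames(df$t_score[i], trimws2(df$feature[i])),
                    df$drug_id[i[1]], df$dose[i[1]]))
    out[unique(key)]
}

#' @rdname readDrugLibrary
#' @param rankings named list of \linkS4class{DrugRanking} objects.
#' @export
writeDrugLibrary <- function(rankings, path) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    rows <- do.call(rbind, lapply(rankings, function(r)
        data.frame(drug_id = r@drugId, dose = r@dose, feature = r@feature,
                   t_score = r@score, stringsAsFactors = FALSE)))
    write.table(rows, path, sep = sep, quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Export enrichment curves for plotting
#'
#' Writes the increased- and decreased-set running curves of an
#' \linkS4class{EnrichmentResult} as one long TSV with columns
#' \code{set}, \code{position}, \code{running_es},
#' \code{theoretical_max}.
#'
#' @param result an \linkS4class{EnrichmentResult}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeEnrichmentCurves <- function(result, path) {
    rows <- do.call(rbind, lapply(names(result@curves), function(nm)
        cbind(set = nm, result@curves[[nm]])))
    write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
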