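#' Screen a drug library against a disease signature
#'
#' Computes the two-set reversal enrichment and its permutation p-value
#' for every drug-dose ranking in the library, attaches
#' Benjamini-Hochberg q-values within the stratum, and ranks rows by
#' reversal score descending, with p-value ascending and then
#' lexicographic drug id / dose as documented tie-breaks. Per-drug
#' permutation seeds are derived deterministically from \code{seed}, so
#' the whole screen is reproducible.
#'
#' @param library list of \linkS4class{DrugRanking} objects.
#' @param signature a \linkS4class{DiseaseSignature}.
#' @param weightExponent,sameSignZero see \code{\link{enrichmentReversal}}.
#' @param nPermutations permutations per drug (default 1000).
#' @param seed integer seed for the whole screen.
#' @param stratum label recorded in the output (e.g. \code{"F.6mo"}).
#' @return data.frame with columns \code{drug_id}, \code{dose},
#'   \code{stratum}, \code{es_increased}, \code{es_decreased},
#'   \code{reversal_score}, \code{p_value}, \code{fdr_q}, \code{rank},
#'   one row per drug-dose, ordered by rank.
#' @export
screenLibrary <- function(library, signature, weightExponent = 1,
        nPermutations = 1000, seed, stratum = NA_character_,
        sameSignZero = TRUE) {
    if (!length(library)) stop("library is empty")
    stopifnot(all(vapply(library, is, logical(1), "DrugRanking")))
    key <- vapply(library, function(r)
        paste(r@drugId, r@dose, sep = "@"), character(1))
    if (anyDuplicated(key))
        stop("duplicate (drug_id, dose) in stratum: ",
             paste(unique(key[duplicated(key)]), collapse = ", "))
    rows <- lapply(seq_along(library), function(i) {
        res <- permutationPValue(library[[i]], signature,
            weightExponent = weightExponent,
            nPermutations = nPermutations,
            seed = deriveSeed(seed, i), sameSignZero = sameSignZero)
        data.frame(drug_id = res@drugId, dose = res@dose,
                   stratum = stratum, es_increased = res@esIncreased,
                   es_decreased = res@esDecreased,
                   reversal_score = res@reversalScore,
                   p_value = res@pValue, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$fdr_q <- p.adjust(tab$p_value, method = "BH")
    ord <- order(-tab$reversal_score, tab$p_value, tab$drug_id, tab$dose)
    tab <- tab[ord, , drop = FALSE]
    tab$rank <- seq_len(nrow(tab))
    rownames(tab) <- NULL
    tab
}

#' Cross-stratum consistency filter
#'
#' Keeps only (drug, dose) pairs predicted as reversers in every stratum
#' (e.g. both sexes): reversal score strictly positive and p (or
#' Benjamini-Hochberg q) at or below \code{alpha} in each screen table.
#' A drug-dose missing from some stratum is dropped with a warning, not
#' an error, since heterogeneous libraries are common.
#'
#' @param tables named list of screen tables from
#'   \code{\link{screenLibrary}} (at least two strata).
#' @param alpha significance threshold (default 0.05).
#' @param by \code{"p"} (raw permutation p, default) or \code{"q"}
#'   (Benjamini-Hochberg within stratum).
#' @return data.frame of kept pairs: \code{drug_id}, \code{dose}, plus
#'   per-stratum reversal scores and p-values, ordered by the mean
#'   reversal score across strata.
#' @export
consistencyFilter <- function(tables, alpha = 0.05, by = c("p", "q")) {
    by <- match.arg(by)
    if (length(tables) < 2) stop("need at least 2 strata")
    if (is.null(names(tables)) || any(!nzchar(names(tables))))
        names(tables) <- paste0("stratum", seq_along(tables))
    keys <- lapply(tables, function(t) paste(t$drug_id, t$dose, sep = "@"))
    shared <- Reduce(intersect, keys)
    all_ <- Reduce(union, keys)
    missing <- setdiff(all_, shared)
    if (length(missing))
        warning(length(missing),
                " (drug, dose) pair(s) absent from some stratum dropped: ",
                paste(missing, collapse = ", "))
    if (!length(shared))
        return(data.frame(drug_id = character(0), dose = numeric(0)))
    stat <- if (by == "p") "p_value" else "fdr_q"
    per <- lapply(names(tables), function(nm) {
        t <- tables[[nm]]
        i <- match(shared, paste(t$drug_id, t$dose, sep = "@"))
        data.frame(sig = t[[stat]][i] <= alpha & t$reversal_score[i] > 0,
                   score = t$reversal_score[i], p = t$p_value[i])
    })
    keep <- Reduce(`&`, lapply(per, `[[`, "sig"))
    first <- tables[[1]]
    i1 <- match(shared, paste(first$drug_id, first$dose, sep = "@"))
    out <- data.frame(drug_id = first$drug_id[i1], dose = first$dose[i1],
                      stringsAsFactors = FALSE)
    for (s in seq_along(per)) {
        out[[paste0("reversal_", names(tables)[s])]] <- per[[s]]$score
        out[[paste0("p_", names(tables)[s])]] <- per[[s]]$p
    }
    out <- out[keep, , drop = FALSE]
    if (nrow(out)) {
        meanScore <- rowMeans(as.matrix(
            out[, grep("^reversal_", names(out)), drop = FALSE]))
        out <- out[order(-meanScore), , drop = FALSE]
    }
    rownames(out) <- NULL
    out
}

#' Write / read a screen table as TSV with a stable column order
#'
#' @param table a screen table from \code{\link{screenLibrary}}.
#' @param path output TSV path.
#' @return \code{path} invisibly (\code{writeScreenTable});
#'   the table (\code{readScreenTable}).
#' @export
writeScreenTable <- function(table, path) {
    cols <- c("drug_id", "dose", "stratum", "es_increased", "es_decreased",
              "reversal_score", "p_value", "fdr_q", "rank")
    write.table(format(table[, intersect(cols, names(table))],
                       digits = 10, trim = TRUE, scientific = FALSE),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeScreenTable
#' @export
readScreenTable <- function(path) {
    read.delim(path, stringsAsFactors = FALSE)
}
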