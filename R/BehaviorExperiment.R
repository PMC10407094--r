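#' Construct a BehaviorExperiment from a samples-by-features table
#'
#' @param values numeric matrix or data.frame, samples in rows, features
#'   in columns, sample ids as rownames.
#' @param metadata data.frame of per-sample metadata (same row order as
#'   \code{values}); must contain a \code{group} column.
#' @param missingPolicy how to resolve missing feature values before
#'   validation: \code{"drop-feature"} removes any feature with a missing
#'   cell (default), \code{"drop-sample"} removes samples instead,
#'   \code{"impute-group-mean"} replaces each missing cell by the mean of
#'   its feature within the sample's group.
#' @return a validated \linkS4class{BehaviorExperiment} (features x samples).
#' @examples
#' vals <- matrix(rnorm(12), 4, 3,
#'     dimnames = list(paste0("m", 1:4), paste0("f", 1:3)))
#' be <- BehaviorExperiment(vals,
#'     data.frame(group = c("WT", "WT", "HD", "HD")))
#' sampleGroups(be)
#' @export
BehaviorExperiment <- function(values, metadata,
        missingPolicy = c("drop-feature", "drop-sample", "impute-group-mean")) {
    missingPolicy <- match.arg(missingPolicy)
    values <- as.matrix(values)
    if (!is.numeric(values))
        stop("feature values must be numeric")
    if (is.null(rownames(values)))
        rownames(values) <- paste0("sample", seq_len(nrow(values)))
    if (is.null(colnames(values)))
        colnames(values) <- paste0("feature", seq_len(ncol(values)))
    colnames(values) <- trimws2(colnames(values))
    metadata <- as.data.frame(metadata)
    if (nrow(metadata) != nrow(values))
        stop("metadata rows must match sample rows")
    if (!"group" %in% colnames(metadata))
        stop("metadata must contain a 'group' column")
    m <- resolveMissing(values, metadata$group, missingPolicy)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(features = t(m$values)),
        colData = S4Vectors::DataFrame(m$metadata %||% metadata,
                                       row.names = rownames(m$values)))
    methods::new("BehaviorExperiment", se)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resolveMissing <- function(values, group, policy) {
    bad <- !is.finite(values)
    if (!any(bad)) return(list(values = values, metadata = NULL))
    if (policy == "drop-feature") {
        keep <- colSums(bad) == 0
        if (!any(keep)) stop("all features have missing values")
        list(values = values[, keep, drop = FALSE], metadata = NULL)
    } else if (policy == "drop-sample") {
        keep <- rowSums(bad) == 0
        if (!any(keep)) stop("all samples have missing values")
        list(values = values[keep, , drop = FALSE], metadata = NULL)
    } else {
        for (g in unique(group)) {
            rows <- which(group == g)
            for (j in which(colSums(bad[rows, , drop = FALSE]) > 0)) {
                v <- values[rows, j]
                fill <- mean(v[is.finite(v)])
                if (!is.finite(fill))
                    stop("feature '", colnames(values)[j],
                         "' entirely missing in group '", g, "'")
                values[rows, j][!is.finite(v)] <- fill
            }
        }
        list(values = values, metadata = NULL)
    }
}

metadataColumns <- c("group", "sex", "age_months", "treatment",
                     "dose_mg_per_kg")

#' Read a behavioral feature matrix from delimited text
#'
#' Expects one row per animal subject and a header row: a sample id
#' column, the metadata columns, then numeric feature columns. The
#' delimiter is auto-detected from the extension (\code{.csv} = comma,
#' anything else = tab).
#'
#' @param path file path.
#' @param metadataCols names of the metadata columns; by default the
#'   recognised set (\code{group}, \code{sex}, \code{age_months},
#'   \code{treatment}, \code{dose_mg_per_kg}) found in the header.
#' @param idCol name of the sample id column (default \code{"sample_id"}).
#' @param missingPolicy see \code{\link{BehaviorExperiment}}.
#' @return a \linkS4class{BehaviorExperiment}.
#' @export
readFeatureMatrix <- function(path, metadataCols = NULL,
        idCol = "sample_id", missingPolicy = "drop-feature") {
    if (!file.exists(path)) stop("no such file: ", path)
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    header <- trimws2(strsplit(readLines(path, n = 1), sep, fixed = TRUE)[[1]])
    dup <- unique(header[duplicated(header)])
    if (length(dup))
        stop("duplicated column name(s): ", paste(dup, collapse = ", "))
    df <- read.delim(path, sep = sep, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df) <- trimws2(colnames(df))
    if (!idCol %in% colnames(df))
        stop("sample id column '", idCol, "' not found")
    if (anyDuplicated(df[[idCol]]))
        stop("duplicate sample id(s): ",
             paste(unique(df[[idCol]][duplicated(df[[idCol]])]), collapse = ", "))
    if (is.null(metadataCols))
        metadataCols <- intersect(metadataColumns, colnames(df))
    missingMeta <- setdiff(metadataCols, colnames(df))
    if (length(missingMeta))
        stop("declared metadata column(s) absent: ",
             paste(missingMeta, collapse = ", "))
    featCols <- setdiff(colnames(df), c(idCol, metadataCols))
    if (!length(featCols)) stop("no feature columns found")
    vals <- as.matrix(df[, featCols, drop = FALSE])
    suppressWarnings(storage.mode(vals) <- "double")
    raw <- df[, featCols, drop = FALSE]
    nonnum <- which(is.na(vals) & !(is.na(raw) | raw == "" | raw == "NA"),
                    arr.ind = TRUE)
    if (nrow(nonnum))
        stop(sprintf("non-numeric feature value at row %d, column '%s'",
             nonnum[1, 1], featCols[nonnum[1, 2]]))
    rownames(vals) <- df[[idCol]]
    be <- BehaviorExperiment(vals, df[, metadataCols, drop = FALSE],
                             missingPolicy = missingPolicy)
    message(sprintf("read %d samples x %d features (%d groups) from %s",
        ncol(be), nrow(be),
        length(unique(SummarizedExperiment::colData(be)$group)),
        basename(path)))
    be
}

#' Write a BehaviorExperiment back to delimited text
#'
#' Inverse of \code{\link{readFeatureMatrix}}: one row per sample, sample
#' id first, then the metadata columns, then the features.
#'
#' @param be a \linkS4class{BehaviorExperiment}.
#' @param path output path; \code{.csv} writes comma-separated, anything
#'   else tab-separated.
#' @param idCol name used for the sample id column.
#' @return \code{path}, invisibly.
#' @export
writeFeatureMatrix <- function(be, path, idCol = "sample_id") {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    cd <- as.data.frame(SummarizedExperiment::colData(be))
    out <- cbind(setNames(data.frame(colnames(be),
                                     stringsAsFactors = FALSE), idCol),
                 cd, as.data.frame(t(SummarizedExperiment::assay(be, "features"))))
    write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Apply a missing-value policy to a raw samples-by-features table
#'
#' Convenience wrapper used by the readers; exported because cohort
#' assembly scripts often need it before constructing the experiment.
#'
#' @param values samples x features matrix, possibly with NA/NaN cells.
#' @param group per-sample group labels (used by group-mean imputation).
#' @param policy one of \code{"drop-feature"}, \code{"drop-sample"},
#'   \code{"impute-group-mean"}.
#' @return a numeric matrix with all cells finite.
#' @export
applyMissingPolicy <- function(values, group,
        policy = c("drop-feature", "drop-sample", "impute-group-mean")) {
    policy <- match.arg(policy)
    resolveMissing(as.matrix(values), group, policy)$values
}
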