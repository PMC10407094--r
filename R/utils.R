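# Internal helpers: seeded RNG scoping, sample selection, validation.

# Evaluate expr under a fixed seed without disturbing the caller's RNG
# stream. All stochastic entry points funnel through this.
withSeed <- function(seed, expr) {
    if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
        stop("seed must be a single integer")
    if (abs(seed) >= 2^31)
        stop("seed must fit a 32-bit integer")
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
    expr
}

# Derive a stream-specific child seed < 2^31 from a top-level seed.
deriveSeed <- function(seed, stream) {
    as.integer((as.double(seed) * 48271 + 7919 * stream) %% 2147483647)
}

# Resolve a sample selector against a BehaviorExperiment. Accepts:
#  - a single string: matched against colData$group
#  - a named list: AND-ed equality filters over colData columns
#  - a logical vector over samples, or a character vector of sample ids
selectSamples <- function(be, selector, what = "selector") {
    cd <- SummarizedExperiment::colData(be)
    ids <- colnames(be)
    idx <- if (is.logical(selector)) {
        if (length(selector) != length(ids))
            stop(what, ": logical selector length must equal sample count")
        which(selector)
    } else if (is.list(selector)) {
        keep <- rep(TRUE, length(ids))
        for (nm in names(selector)) {
            if (!nm %in% colnames(cd))
                stop(what, ": no metadata column '", nm, "'")
            keep <- keep & (as.character(cd[[nm]]) %in% as.character(selector[[nm]]))
        }
        which(keep)
    } else if (is.character(selector) && all(selector %in% ids)) {
        match(selector, ids)
    } else if (is.character(selector) && length(selector) == 1) {
        which(as.character(cd$group) == selector)
    } else {
        stop(what, ": cannot interpret selector")
    }
    if (!length(idx))
        stop(what, " matched 0 samples")
    idx
}

# Feature sub-matrix (features x samples) for a selector.
groupMatrix <- function(be, selector, what = "selector") {
    idx <- selectSamples(be, selector, what)
    SummarizedExperiment::assay(be, "features")[, idx, drop = FALSE]
}

selectorLabel <- function(selector) {
    if (is.character(selector) && length(selector) == 1) selector
    else if (is.list(selector))
        paste(vapply(names(selector), function(nm)
            paste0(nm, "=", paste(selector[[nm]], collapse = "|")),
            character(1)), collapse = ",")
    else "custom"
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

trimws2 <- function(x) trimws(as.character(x))
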