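## Genus-name normalization shared by all readers and constructors:
## trim whitespace, strip a leading rank prefix of the form "g__".
## Matching is case-sensitive afterwards.
normalizeGenus <- function(x) {
    x <- trimws(x)
    sub("^[a-zA-Z]__", "", x)
}

## Evaluate `expr` under `seed` without disturbing the caller's RNG state.
withLocalSeed <- function(seed, expr) {
    genv <- globalenv()
    had <- exists(".Random.seed", envir = genv, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = genv) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = genv)
        else if (exists(".Random.seed", envir = genv, inherits = FALSE))
            rm(".Random.seed", envir = genv)
    })
    set.seed(seed)
    force(expr)
}

## Deterministic category order: lexicographic (C locale), the reserved
## unidentified category always last.
orderCategories <- function(categories) {
    categories <- unique(categories)
    has.na <- .UNIDENTIFIED %in% categories
    rest <- setdiff(categories, .UNIDENTIFIED)
    rest <- rest[order(rest, method = "radix")]
    c(rest, if (has.na) .UNIDENTIFIED)
}

## Sample standard error: SD with n-1 denominator over sqrt(n).
sampleSE <- function(x) stats::sd(x) / sqrt(length(x))

logInfo <- function(verbose, ...) {
    if (isTRUE(verbose)) message("INFO: ", sprintf(...))
}
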