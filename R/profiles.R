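#' Construct a genus-level count table
#'
#' @param counts Named numeric vector of non-negative read counts (at least
#'   one positive). Names are trimmed and rank prefixes stripped.
#' @param communityId Community identifier.
#' @return A [CountTable-class].
#' @examples
#' countTable(c(Bacteroides = 120, Escherichia = 80), "demo")
#' @export
countTable <- function(counts, communityId = "") {
    names(counts) <- normalizeGenus(names(counts))
    new("CountTable", counts = counts, communityId = communityId)
}

#' Construct a relative-abundance profile
#'
#' Abundances summing to 1 within 1e-6 are renormalized exactly onto the
#' simplex (expected-composition files typically carry rounding); larger
#' deviations are rejected.
#'
#' @param abundances Named numeric vector of non-negative relative
#'   abundances summing to 1 (within 1e-6).
#' @param communityId Community identifier.
#' @return A [TaxonProfile-class].
#' @examples
#' taxonProfile(c(A = 0.25, B = 0.75))
#' @export
taxonProfile <- function(abundances, communityId = "") {
    names(abundances) <- normalizeGenus(names(abundances))
    tot <- sum(abundances)
    if (is.na(tot) || abs(tot - 1) > 1e-6)
        stop(sprintf("abundances must sum to 1 within 1e-6 (got %.8f)", tot))
    new("TaxonProfile", abundances = abundances / tot,
        communityId = communityId)
}

#' Divide genus counts by their 16S gene copy numbers
#'
#' The core normalization step: each genus count is divided by its mean
#' copy number from \code{db}, or by the database default when the genus
#' has no entry (always the case for the unidentified category). Output
#' keys and order are identical to the input.
#'
#' @param counts A [CountTable-class].
#' @param db A [GCNDatabase-class].
#' @param verbose Log which genera received the default copy number.
#' @return A [CountTable-class] of corrected (generally fractional) counts.
#' @examples
#' ct <- countTable(c(A = 100, B = 100))
#' gcnCorrect(ct, gcnDatabase(c(A = 4, B = 2)))
#' @export
gcnCorrect <- function(counts, db, verbose = FALSE) {
    stopifnot(is(counts, "CountTable"), is(db, "GCNDatabase"))
    genera <- names(counts@counts)
    gcn <- lookupGCN(db, genera)
    defaulted <- !(normalizeGenus(genera) %in% names(db@entries))
    if (any(defaulted))
        logInfo(verbose, "default copy number %.3g applied to: %s",
                db@defaultGCN, paste(genera[defaulted], collapse = ", "))
    new("CountTable", counts = counts@counts / gcn,
        communityId = counts@communityId)
}

#' Convert counts to relative abundances
#'
#' Divides every count by the total of the same table, so raw counts are
#' normalized by the raw total and copy-number-corrected counts by the
#' corrected total; either way the result lies on the simplex.
#'
#' @param counts A [CountTable-class] with positive total.
#' @return A [TaxonProfile-class].
#' @examples
#' toRelative(countTable(c(A = 25, B = 50)))
#' @export
toRelative <- function(counts) {
    stopifnot(is(counts, "CountTable"))
    tot <- sum(counts@counts)
    if (tot <= 0) stop("cannot normalize a table with zero total count")
    new("TaxonProfile", abundances = counts@counts / tot,
        communityId = counts@communityId)
}

#' Align two profiles on the union of their categories
#'
#' Categories are the sorted union (lexicographic, unidentified last);
#' a category absent from one profile gets abundance 0 on that side. Mock
#' compositions contain no unidentified category by construction, so the
#' expected abundance of the unidentified category is always 0.
#'
#' @param observed,expected [TaxonProfile-class] objects.
#' @return An [AlignedPair-class].
#' @examples
#' alignProfiles(taxonProfile(c(A = 1)), taxonProfile(c(B = 1)))
#' @export
alignProfiles <- function(observed, expected) {
    stopifnot(is(observed, "TaxonProfile"), is(expected, "TaxonProfile"))
    cats <- orderCategories(c(names(observed@abundances),
                              names(expected@abundances)))
    pick <- function(p) {
        v <- p@abundances[cats]
        v[is.na(v)] <- 0
        unname(v)
    }
    new("AlignedPair", categories = cats, expected = pick(expected),
        observed = pick(observed))
}

#' Residual sum of squares between two relative-abundance profiles
#'
#' The fit statistic of the benchmark:
#' \deqn{\mathrm{RSS} = \sum_i (y_i - f(x_i))^2}
#' summed over the aligned union of genus categories, where \eqn{y_i} is
#' the expected (mock) abundance and \eqn{f(x_i)} the observed raw or
#' copy-number-corrected abundance of category \eqn{i}. The unidentified
#' category participates with expected abundance 0, which is what lets
#' a default copy number far below the community's true copy numbers
#' inflate the corrected RSS. Bounded by \[0, 2\]; 0 exactly when the
#' profiles agree on the union.
#'
#' @param observed,expected [TaxonProfile-class] objects.
#' @return Non-negative scalar.
#' @examples
#' rss(taxonProfile(c(A = 0.6, B = 0.4)), taxonProfile(c(A = 0.5, B = 0.5)))
#' @export
rss <- function(observed, expected) {
    ap <- alignProfiles(observed, expected)
    sum((ap@expected - ap@observed)^2)
}
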