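#' Shannon diversity of a genus-level profile
#'
#' \eqn{-\sum_i p_i \log p_i} over categories with positive abundance,
#' computed with \code{vegan::diversity}. The natural logarithm is the
#' default (the \pkg{vegan} convention); \code{base} is exposed for
#' sensitivity checks. The unidentified category counts as one category
#' when present -- it is part of the sequenced composition -- but can be
#' dropped with \code{includeUnidentified = FALSE}.
#'
#' @param profile A [TaxonProfile-class].
#' @param base Logarithm base; \code{exp(1)} for nats.
#' @param includeUnidentified Keep the unidentified category as a category.
#' @return Non-negative scalar; 0 for a single-category profile.
#' @examples
#' shannonDiversity(taxonProfile(c(A = 0.25, B = 0.25, C = 0.25, D = 0.25)))
#' log(4)
#' @export
shannonDiversity <- function(profile, base = exp(1),
                             includeUnidentified = TRUE) {
    stopifnot(is(profile, "TaxonProfile"))
    p <- profile@abundances
    if (!includeUnidentified)
        p <- p[names(p) != .UNIDENTIFIED]
    p <- p[p > 0]
    if (length(p) == 0L) return(0)
    unname(vegan::diversity(p / sum(p), index = "shannon", base = base))
}

#' Genus richness of a profile
#'
#' The number of genera with strictly positive abundance. The unidentified
#' category is never a genus and is excluded.
#'
#' @param profile A [TaxonProfile-class].
#' @return Integer count.
#' @examples
#' genusRichness(taxonProfile(c(A = 0.999, Unidentified = 0.001)))
#' @export
genusRichness <- function(profile) {
    stopifnot(is(profile, "TaxonProfile"))
    p <- profile@abundances
    p <- p[names(p) != .UNIDENTIFIED]
    sum(p > 0)
}

#' Misidentification fractions of an observed profile
#'
#' Quantifies the two misassignment routes of an amplicon pipeline against
#' a known mock composition, on the raw (uncorrected) relative profile:
#' \code{naFrac} is the abundance of the unidentified category, and
#' \code{otherFrac} the summed abundance of genera that the mock does not
#' contain (unidentified excluded).
#'
#' @param observed Observed raw [TaxonProfile-class].
#' @param mock Expected mock [TaxonProfile-class].
#' @return List with components \code{naFrac} and \code{otherFrac}, both
#'   in \[0, 1\] with sum at most 1.
#' @examples
#' obs <- taxonProfile(c(A = 0.90, C = 0.06, Unidentified = 0.04))
#' misidentification(obs, taxonProfile(c(A = 0.5, B = 0.5)))
#' @export
misidentification <- function(observed, mock) {
    stopifnot(is(observed, "TaxonProfile"), is(mock, "TaxonProfile"))
    p <- observed@abundances
    naFrac <- unname(sum(p[names(p) == .UNIDENTIFIED]))
    expected <- mock@abundances[mock@abundances > 0]
    other <- setdiff(names(p), c(names(expected), .UNIDENTIFIED))
    list(naFrac = naFrac, otherFrac = unname(sum(p[other])))
}

#' Shannon-ratio exclusion rule for unreliable communities
#'
#' A sequencing run that recovers only a small fraction of the mock's
#' diversity makes the fit comparison meaningless; such communities are
#' excluded. A community is excluded when the ratio of its raw Shannon
#' diversity to the mock's falls strictly below \code{threshold}; a ratio
#' exactly at the threshold is kept.
#'
#' @param shannonRaw Shannon diversity of the observed raw profile.
#' @param shannonMock Shannon diversity of the mock (must be > 0).
#' @param threshold Ratio cutoff in (0, 1); default 0.25, which excludes
#'   a community recovering about a fifth of the mock diversity while
#'   keeping every credible run.
#' @return \code{TRUE} when the community should be excluded.
#' @examples
#' excludeCommunity(0.3926, 2.0736)  # ratio ~0.19 -> TRUE
#' excludeCommunity(2.69, 2.82)      # -> FALSE
#' @export
excludeCommunity <- function(shannonRaw, shannonMock, threshold = 0.25) {
    if (shannonMock <= 0)
        stop("'shannonMock' must be > 0 to form the diversity ratio")
    stopifnot(threshold > 0, threshold < 1)
    (shannonRaw / shannonMock) < threshold
}
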