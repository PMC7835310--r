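#' @import methods
NULL

## Canonical reserved category for reads that could not be assigned at genus
## level. IO readers map a configurable token onto this constant.
.UNIDENTIFIED <- "Unidentified"

#' Reserved category label for unassigned reads
#'
#' Genus-level amplicon profiles carry a reserved category for reads whose
#' taxonomy could not be resolved at genus level. All \pkg{gcnbench}
#' operations recognise this label; file readers map a user-configurable
#' token onto it.
#'
#' @return A length-one character string, the canonical label.
#' @examples
#' unidentifiedToken()
#' @export
unidentifiedToken <- function() .UNIDENTIFIED

#' Class \code{GCNDatabase}: genus-level 16S copy-number lookup
#'
#' Maps genus names to mean 16S rRNA gene copy numbers (copies per genome)
#' and carries a default copy number applied to genera without an entry,
#' including the reserved unidentified category.
#'
#' @slot entries Named numeric vector, genus name to mean copy number;
#'   all values strictly positive, names unique and non-empty.
#' @slot defaultGCN Positive scalar applied to genera absent from
#'   \code{entries}. The conventional value is 1.8 copies per genome.
#' @slot sourceLabel Free-text provenance label for the table.
#'
#' @seealso [gcnDatabase()], [loadGCNTable()], [lookupGCN()]
#' @export
setClass("GCNDatabase",
    representation(entries = "numeric", defaultGCN = "numeric",
                   sourceLabel = "character"))

setValidity("GCNDatabase", function(object) {
    e <- object@entries
    if (length(e) && is.null(names(e)))
        return("'entries' must be a named numeric vector")
    if (length(e) && (anyNA(names(e)) || any(!nzchar(names(e)))))
        return("genus names must be non-empty")
    if (length(e) && anyDuplicated(names(e)))
        return("duplicate genus names in 'entries'")
    if (anyNA(e) || any(e <= 0))
        return("every copy number must be > 0")
    if (length(object@defaultGCN) != 1L || is.na(object@defaultGCN) ||
        object@defaultGCN <= 0)
        return("'defaultGCN' must be a single positive number")
    TRUE
})

#' Class \code{CountTable}: genus-level read counts for one community
#'
#' Non-negative read counts per genus for a single community or sample.
#' Counts may be real-valued (copy-number-corrected counts are fractional).
#' The reserved unidentified category may appear as a key.
#'
#' @slot counts Named numeric vector of non-negative counts with at least
#'   one positive entry; names unique and non-empty.
#' @slot communityId Free-text community identifier.
#'
#' @seealso [countTable()], [gcnCorrect()], [toRelative()]
#' @export
setClass("CountTable",
    representation(counts = "numeric", communityId = "character"))

setValidity("CountTable", function(object) {
    x <- object@counts
    if (length(x) == 0L) return("at least one genus is required")
    if (is.null(names(x)) || anyNA(names(x)) || any(!nzchar(names(x))))
        return("counts must have non-empty genus names")
    if (anyDuplicated(names(x))) return("duplicate genus names")
    if (anyNA(x) || any(x < 0)) return("all counts must be >= 0")
    if (sum(x) <= 0) return("at least one count must be > 0")
    TRUE
})

#' Class \code{TaxonProfile}: genus-level relative abundances
#'
#' A composition over genera (plus, optionally, the reserved unidentified
#' category) that sums to one. This is the common currency of the fit
#' statistic: the expected mock composition and the observed raw or
#' copy-number-corrected profiles are all \code{TaxonProfile}s.
#'
#' @slot abundances Named numeric vector in \[0, 1\] summing to 1 (within
#'   1e-9); names unique and non-empty.
#' @slot communityId Free-text community identifier.
#'
#' @seealso [taxonProfile()], [rss()], [shannonDiversity()]
#' @export
setClass("TaxonProfile",
    representation(abundances = "numeric", communityId = "character"))

setValidity("TaxonProfile", function(object) {
    p <- object@abundances
    if (length(p) == 0L) return("at least one category is required")
    if (is.null(names(p)) || anyNA(names(p)) || any(!nzchar(names(p))))
        return("abundances must have non-empty genus names")
    if (anyDuplicated(names(p))) return("duplicate genus names")
    if (anyNA(p) || any(p < 0)) return("abundances must be >= 0")
    if (abs(sum(p) - 1) > 1e-9)
        return(sprintf("abundances must sum to 1 (got %.12f)", sum(p)))
    TRUE
})

#' Class \code{AlignedPair}: two profiles on a common category index
#'
#' Deterministic alignment of an observed and an expected profile over the
#' union of their categories (lexicographic order, unidentified last),
#' with zeros filled in where a category is absent on one side.
#'
#' @slot categories Character vector of aligned category names.
#' @slot expected Numeric vector of expected (mock) abundances.
#' @slot observed Numeric vector of observed abundances.
#'
#' @seealso [alignProfiles()]
#' @export
setClass("AlignedPair",
    representation(categories = "character", expected = "numeric",
                   observed = "numeric"))

setValidity("AlignedPair", function(object) {
    n <- length(object@categories)
    if (length(object@expected) != n || length(object@observed) != n)
        return("'categories', 'expected' and 'observed' must share a length")
    if (abs(sum(object@expected) - 1) > 1e-9 ||
        abs(sum(object@observed) - 1) > 1e-9)
        return("aligned vectors must each sum to 1")
    TRUE
})

#' Class \code{CommunityEvaluation}: one benchmark row
#'
#' The full per-community record of the benchmark: misidentification
#' fractions, Shannon diversity (mock, raw, copy-number-corrected), genus
#' richness (mock, raw), the residual sum of squares of the raw and
#' corrected profiles against the mock, the exclusion flag and the
#' best-fitting pipeline.
#'
#' @slot communityId Community identifier.
#' @slot naFrac Fraction of reads in the unidentified category (raw profile).
#' @slot otherFrac Fraction of reads assigned to genera absent from the mock.
#' @slot shannonMock,shannonRaw,shannonGCN Shannon diversity (natural log).
#' @slot richnessMock,richnessRaw Number of genera with positive abundance
#'   (unidentified excluded).
#' @slot rssRaw,rssGCN Residual sum of squares against the mock profile.
#' @slot excluded Whether the community is dropped from cohort aggregation.
#' @slot bestFit \code{"raw"} or \code{"gcn"}; \code{"gcn"} only when
#'   correction strictly lowers the RSS.
#'
#' @seealso [evaluateCommunity()], [aggregateCohort()],
#'   [referenceEvaluations()]
#' @export
setClass("CommunityEvaluation",
    representation(communityId = "character",
                   naFrac = "numeric", otherFrac = "numeric",
                   shannonMock = "numeric", shannonRaw = "numeric",
                   shannonGCN = "numeric",
                   richnessMock = "integer", richnessRaw = "integer",
                   rssRaw = "numeric", rssGCN = "numeric",
                   excluded = "logical", bestFit = "character"))

setValidity("CommunityEvaluation", function(object) {
    fr <- c(object@naFrac, object@otherFrac)
    if (anyNA(fr) || any(fr < 0) || any(fr > 1))
        return("fractions must lie in [0, 1]")
    if (object@naFrac + object@otherFrac > 1 + 1e-9)
        return("naFrac + otherFrac must not exceed 1")
    if (object@rssRaw < 0 || object@rssGCN < 0)
        return("RSS values must be >= 0")
    if (object@richnessMock < 1L || object@richnessRaw < 1L)
        return("richness must be >= 1")
    if (!object@bestFit %in% c("raw", "gcn"))
        return("'bestFit' must be \"raw\" or \"gcn\"")
    ## ties go to raw: gcn must strictly improve the fit
    want <- if (object@rssGCN < object@rssRaw) "gcn" else "raw"
    if (object@bestFit != want)
        return("'bestFit' inconsistent with the RSS pair (ties go to raw)")
    TRUE
})

#' Class \code{CohortSummary}: cohort-level aggregates
#'
#' Mean and standard error (sample SD over the square root of n) of the
#' per-community quantities across retained communities, all on the
#' percentage scale, plus the number of communities where the uncorrected
#' profile fits the mock strictly better.
#'
#' @slot n Number of retained communities.
#' @slot meanRssDiffPct,seRssDiffPct Mean/SE of 100 * (rssGCN - rssRaw):
#'   positive means the uncorrected profile fits better.
#' @slot meanRichnessOverrepPct,seRichnessOverrepPct Mean/SE of
#'   100 * (richnessRaw - richnessMock) / richnessMock.
#' @slot meanNaPct,seNaPct Mean/SE of the unidentified fraction, percent.
#' @slot meanOtherPct,seOtherPct Mean/SE of the other-genera fraction,
#'   percent.
#' @slot nRawBetter Communities with rssRaw < rssGCN.
#'
#' @seealso [aggregateCohort()]
#' @export
setClass("CohortSummary",
    representation(n = "integer",
                   meanRssDiffPct = "numeric", seRssDiffPct = "numeric",
                   meanRichnessOverrepPct = "numeric",
                   seRichnessOverrepPct = "numeric",
                   meanNaPct = "numeric", seNaPct = "numeric",
                   meanOtherPct = "numeric", seOtherPct = "numeric",
                   nRawBetter = "integer"))

setValidity("CohortSummary", function(object) {
    if (object@n < 2L) return("'n' must be >= 2 for standard errors")
    if (object@nRawBetter > object@n)
        return("'nRawBetter' cannot exceed 'n'")
    TRUE
})

#' Class \code{SyntheticMock}: a simulated mock-community experiment
#'
#' Ground truth plus the observed outcome of one simulated sequencing run:
#' the true composition, the per-genus copy numbers used as sampling bias,
#' the multinomially drawn observed counts, and the simulation parameters.
#'
#' @slot truth \code{TaxonProfile} of the true composition over real genera.
#' @slot copyNumbers Named numeric vector of copy numbers for every genus
#'   that can emit reads (real and spurious).
#' @slot observed \code{CountTable} of the drawn reads (total equals the
#'   requested depth).
#' @slot params List of the simulation parameters, including the seed.
#'
#' @seealso [simulateMock()], [scenarioMock19()]
#' @export
setClass("SyntheticMock",
    representation(truth = "TaxonProfile", copyNumbers = "numeric",
                   observed = "CountTable", params = "list"))

setValidity("SyntheticMock", function(object) {
    depth <- object@params$depth
    if (!is.null(depth) && sum(object@observed@counts) != depth)
        return("observed total must equal the requested depth")
    known <- c(names(object@truth@abundances), names(object@copyNumbers),
               .UNIDENTIFIED)
    if (!all(names(object@observed@counts) %in% known))
        return("observed categories must be true, spurious or unidentified")
    TRUE
})
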