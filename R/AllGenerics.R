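#' @rdname accessors
#' @export
setGeneric("communityId", function(x) standardGeneric("communityId"))

#' @rdname accessors
#' @export
setGeneric("genusCounts", function(x) standardGeneric("genusCounts"))

#' @rdname accessors
#' @export
setGeneric("genusAbundances", function(x) standardGeneric("genusAbundances"))

#' @rdname accessors
#' @export
setGeneric("gcnEntries", function(x) standardGeneric("gcnEntries"))

#' @rdname accessors
#' @export
setGeneric("defaultGCN", function(x) standardGeneric("defaultGCN"))

#' @rdname accessors
#' @export
setGeneric("sourceLabel", function(x) standardGeneric("sourceLabel"))

#' @rdname accessors
#' @export
setGeneric("mockTruth", function(x) standardGeneric("mockTruth"))

#' @rdname accessors
#' @export
setGeneric("copyNumbers", function(x) standardGeneric("copyNumbers"))

#' @rdname accessors
#' @export
setGeneric("observedCounts", function(x) standardGeneric("observedCounts"))

#' @rdname accessors
#' @export
setGeneric("simParams", function(x) standardGeneric("simParams"))

#' Accessors for gcnbench classes
#'
#' Slot accessors: \code{communityId} for \code{CountTable},
#' \code{TaxonProfile} and \code{CommunityEvaluation}; \code{genusCounts}
#' for \code{CountTable}; \code{genusAbundances} for \code{TaxonProfile};
#' \code{gcnEntries}, \code{defaultGCN} and \code{sourceLabel} for
#' \code{GCNDatabase}; \code{mockTruth}, \code{copyNumbers},
#' \code{observedCounts} and \code{simParams} for \code{SyntheticMock}.
#'
#' @param x An object of the matching class.
#' @return The slot value: a character scalar, named numeric vector,
#'   \code{TaxonProfile}, \code{CountTable} or list as appropriate.
#' @examples
#' ct <- countTable(c(A = 10, B = 30), "demo")
#' genusCounts(ct)
#' communityId(ct)
#' @name accessors
#' @aliases communityId genusCounts genusAbundances gcnEntries defaultGCN
#'   sourceLabel mockTruth copyNumbers observedCounts simParams
NULL

setMethod("communityId", "CountTable", function(x) x@communityId)
setMethod("communityId", "TaxonProfile", function(x) x@communityId)
setMethod("communityId", "CommunityEvaluation", function(x) x@communityId)
setMethod("genusCounts", "CountTable", function(x) x@counts)
setMethod("genusAbundances", "TaxonProfile", function(x) x@abundances)
setMethod("gcnEntries", "GCNDatabase", function(x) x@entries)
setMethod("defaultGCN", "GCNDatabase", function(x) x@defaultGCN)
setMethod("sourceLabel", "GCNDatabase", function(x) x@sourceLabel)
setMethod("mockTruth", "SyntheticMock", function(x) x@truth)
setMethod("copyNumbers", "SyntheticMock", function(x) x@copyNumbers)
setMethod("observedCounts", "SyntheticMock", function(x) x@observed)
setMethod("simParams", "SyntheticMock", function(x) x@params)

setMethod("show", "GCNDatabase", function(object) {
    cat(sprintf("GCNDatabase with %d genera (default %.3g copies/genome)\n",
                length(object@entries), object@defaultGCN))
    if (nzchar(object@sourceLabel))
        cat("  source:", object@sourceLabel, "\n")
})

setMethod("show", "CountTable", function(object) {
    cat(sprintf("CountTable '%s': %d categories, %.6g reads\n",
                object@communityId, length(object@counts),
                sum(object@counts)))
})

setMethod("show", "TaxonProfile", function(object) {
    cat(sprintf("TaxonProfile '%s': %d categories\n",
                object@communityId, length(object@abundances)))
    top <- sort(object@abundances, decreasing = TRUE)
    top <- utils::head(top, 5L)
    for (g in names(top))
        cat(sprintf("  %-25s %.4f\n", g, top[[g]]))
    if (length(object@abundances) > 5L) cat("  ...\n")
})

setMethod("show", "CommunityEvaluation", function(object) {
    cat(sprintf("CommunityEvaluation '%s'%s\n", object@communityId,
                if (object@excluded) " [excluded]" else ""))
    cat(sprintf("  misidentified: NA %.4f, other genera %.4f\n",
                object@naFrac, object@otherFrac))
    cat(sprintf("  Shannon: mock %.4f, raw %.4f, GCN %.4f\n",
                object@shannonMock, object@shannonRaw, object@shannonGCN))
    cat(sprintf("  richness: mock %d, raw %d\n",
                object@richnessMock, object@richnessRaw))
    cat(sprintf("  RSS: raw %.4f, GCN %.4f -> best fit %s\n",
                object@rssRaw, object@rssGCN, object@bestFit))
})

setMethod("show", "CohortSummary", function(object) {
    cat(sprintf("CohortSummary over %d communities\n", object@n))
    cat(sprintf("  RSS(GCN) - RSS(raw): %.1f%% (SE %.1f%%)\n",
                object@meanRssDiffPct, object@seRssDiffPct))
    cat(sprintf("  richness overrepresentation: %.1f%% (SE %.1f%%)\n",
                object@meanRichnessOverrepPct, object@seRichnessOverrepPct))
    cat(sprintf("  unidentified reads: %.1f%% (SE %.1f%%)\n",
                object@meanNaPct, object@seNaPct))
    cat(sprintf("  other genera: %.1f%% (SE %.1f%%)\n",
                object@meanOtherPct, object@seOtherPct))
    cat(sprintf("  raw fits better in %d of %d communities\n",
                object@nRawBetter, object@n))
})

setMethod("show", "SyntheticMock", function(object) {
    p <- object@params
    cat(sprintf("SyntheticMock '%s': %d true genera, depth %d, seed %s\n",
                object@truth@communityId,
                length(object@truth@abundances),
                as.integer(sum(object@observed@counts)),
                if (is.null(p$seed)) "?" else format(p$seed)))
})
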