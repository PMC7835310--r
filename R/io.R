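## Shared delimited-file reader: '#' comment lines ignored, delimiter
## auto-detected between tab and comma, header line skipped when present.
## Returns the split data rows together with their original line numbers
## so errors can name the offending line.
readDelimited <- function(path, what = "table", header = TRUE) {
    if (!file.exists(path))
        stop("cannot read ", what, ": no such file '", path, "'")
    lines <- readLines(path, warn = FALSE)
    keep <- which(!grepl("^\\s*(#|$)", lines))
    if (length(keep) == 0L)
        stop("empty ", what, ": '", path, "'")
    delim <- if (grepl("\t", lines[keep[1L]])) "\t" else ","
    if (header) keep <- keep[-1L]
    list(rows = strsplit(lines[keep], delim, fixed = TRUE),
         lineno = keep, delim = delim)
}

#' Read an expected mock composition in the mockrobiota dialect
#'
#' Parses a two-column taxonomy file as distributed by the mockrobiota
#' repository: a semicolon-delimited lineage and a relative abundance,
#' comma- or tab-delimited (auto-detected), with an optional header. The
#' genus is the last non-empty rank at or above genus (rank prefixes such
#' as \code{"g__"} are stripped; species-level fields prefixed
#' \code{"s__"} are ignored). Entries collapsing to the same genus are
#' summed. The abundance column must sum to 1 within 1e-3 (files carry
#' rounding); the result is renormalized exactly onto the simplex.
#'
#' @param path Path to the taxonomy file.
#' @param communityId Community identifier for the returned profile;
#'   defaults to the file's base name without extension.
#' @return A [TaxonProfile-class] of the expected composition.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("Bacteria;Bacteroidetes;g__Bacteroides,0.4",
#'              "Bacteria;Proteobacteria;g__Escherichia,0.6"), tf)
#' readMockrobiotaTaxonomy(tf)
#' @export
readMockrobiotaTaxonomy <- function(path,
                                    communityId = sub("\\.[^.]*$", "",
                                                      basename(path))) {
    fields <- readDelimited(path, what = "taxonomy file", header = FALSE)
    genus <- character(0)
    abund <- numeric(0)
    for (i in seq_along(fields$rows)) {
        row <- fields$rows[[i]]
        if (length(row) < 2L)
            stop(sprintf("line %d of '%s': expected lineage and abundance",
                         fields$lineno[i], path))
        val <- suppressWarnings(as.numeric(row[[length(row)]]))
        if (is.na(val)) {
            if (i == 1L) next  # header line
            stop(sprintf("line %d of '%s': non-numeric abundance '%s'",
                         fields$lineno[i], path, row[[length(row)]]))
        }
        if (val < 0)
            stop(sprintf("line %d of '%s': negative abundance",
                         fields$lineno[i], path))
        ranks <- trimws(strsplit(row[[1L]], ";", fixed = TRUE)[[1L]])
        ranks <- ranks[!grepl("^s__", ranks)]  # at or above genus only
        ranks <- normalizeGenus(ranks)
        ranks <- ranks[nzchar(ranks)]
        if (length(ranks) == 0L)
            stop(sprintf("line %d of '%s': empty lineage",
                         fields$lineno[i], path))
        genus <- c(genus, ranks[[length(ranks)]])
        abund <- c(abund, val)
    }
    if (length(genus) == 0L)
        stop("no taxa parsed from '", path, "'")
    total <- sum(abund)
    if (abs(total - 1) > 1e-3)
        stop(sprintf("abundances in '%s' sum to %.6f, not 1: corrupt file",
                     path, total))
    collapsed <- vapply(split(abund, genus), sum, numeric(1))
    new("TaxonProfile", abundances = collapsed[orderCategories(names(collapsed))] / total,
        communityId = communityId)
}

#' Read a genus-level count table
#'
#' Two-column delimited table (tab or comma, auto-detected) with a header:
#' genus, count. Counts must be non-negative numbers; malformed rows raise
#' an error naming the line. The \code{unidentified} token (default
#' \code{"Unidentified"}) is mapped onto the package's reserved category.
#'
#' @param path Path to the count table.
#' @param communityId Community identifier; defaults to the file's base
#'   name without extension.
#' @param unidentified Token in the file marking unassigned reads.
#' @return A [CountTable-class].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("genus\tcount", "Bacteroides\t120", "unassigned\t7"), tf)
#' readCountTable(tf, unidentified = "unassigned")
#' @export
readCountTable <- function(path,
                           communityId = sub("\\.[^.]*$", "", basename(path)),
                           unidentified = .UNIDENTIFIED) {
    fields <- readDelimited(path, what = "count table")
    genus <- character(0)
    n <- numeric(0)
    for (i in seq_along(fields$rows)) {
        row <- fields$rows[[i]]
        if (length(row) < 2L)
            stop(sprintf("line %d of '%s': expected 2 columns",
                         fields$lineno[i], path))
        val <- suppressWarnings(as.numeric(row[[2L]]))
        if (is.na(val))
            stop(sprintf("line %d of '%s': non-numeric count '%s'",
                         fields$lineno[i], path, row[[2L]]))
        if (val < 0)
            stop(sprintf("line %d of '%s': negative count %s",
                         fields$lineno[i], path, row[[2L]]))
        g <- trimws(row[[1L]])
        if (identical(g, unidentified)) g <- .UNIDENTIFIED
        genus <- c(genus, g)
        n <- c(n, val)
    }
    countTable(stats::setNames(n, genus), communityId = communityId)
}

#' Write a count table as TSV
#'
#' Deterministic writer: categories in lexicographic order with the
#' unidentified category last, tab-delimited, full double precision.
#' Writing the same object twice produces identical bytes.
#'
#' @param counts A [CountTable-class].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeCountTable <- function(counts, path) {
    stopifnot(is(counts, "CountTable"))
    x <- counts@counts[orderCategories(names(counts@counts))]
    writeLines(c("genus\tcount",
                 sprintf("%s\t%.17g", names(x), unname(x))), path)
    invisible(path)
}

#' Write a mock composition in the mockrobiota dialect
#'
#' Emits a two-column CSV of lineage (a bare \code{"g__"}-prefixed genus)
#' and relative abundance, so simulated truths can ride the same input
#' path as real expected-composition files.
#'
#' @param profile A [TaxonProfile-class] (must not contain the
#'   unidentified category: mocks have none by construction).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeMockTaxonomy <- function(profile, path) {
    stopifnot(is(profile, "TaxonProfile"))
    p <- profile@abundances
    if (.UNIDENTIFIED %in% names(p))
        stop("a mock composition cannot contain the unidentified category")
    p <- p[orderCategories(names(p))]
    writeLines(sprintf("g__%s,%.17g", names(p), unname(p)), path)
    invisible(path)
}

#' Write the benchmark report files
#'
#' Writes \code{evaluations.tsv} (one row per community, mirroring the
#' benchmark columns plus best-fit and exclusion flags) and, when a
#' summary is given, \code{cohort_summary.tsv}. Output is deterministic:
#' identical inputs give identical bytes.
#'
#' @param results List of [CommunityEvaluation-class] objects.
#' @param dir Output directory (created if missing).
#' @param summary Optional [CohortSummary-class].
#' @return Character vector of the files written, invisibly.
#' @export
writeEvaluationReport <- function(results, dir, summary = NULL) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    tab <- evaluationTable(results)
    evalPath <- file.path(dir, "evaluations.tsv")
    lines <- c(paste(colnames(tab), collapse = "\t"),
               vapply(seq_len(nrow(tab)), function(i) paste(
                   c(tab$community_id[i],
                     sprintf("%.4f", tab$na_frac[i]),
                     sprintf("%.4f", tab$other_frac[i]),
                     sprintf("%.4f", tab$shannon_mock[i]),
                     sprintf("%.4f", tab$shannon_raw[i]),
                     sprintf("%.4f", tab$shannon_gcn[i]),
                     sprintf("%d", tab$richness_mock[i]),
                     sprintf("%d", tab$richness_raw[i]),
                     sprintf("%.4f", tab$rss_raw[i]),
                     sprintf("%.4f", tab$rss_gcn[i]),
                     tab$best_fit[i],
                     if (tab$excluded[i]) "TRUE" else "FALSE"),
                   collapse = "\t"), character(1)))
    writeLines(lines, evalPath)
    files <- evalPath
    if (!is.null(summary)) {
        stopifnot(is(summary, "CohortSummary"))
        sumPath <- file.path(dir, "cohort_summary.tsv")
        writeLines(c(
            "statistic\tvalue",
            sprintf("n\t%d", summary@n),
            sprintf("mean_rss_diff_pct\t%.4f", summary@meanRssDiffPct),
            sprintf("se_rss_diff_pct\t%.4f", summary@seRssDiffPct),
            sprintf("mean_richness_overrep_pct\t%.4f",
                    summary@meanRichnessOverrepPct),
            sprintf("se_richness_overrep_pct\t%.4f",
                    summary@seRichnessOverrepPct),
            sprintf("mean_na_pct\t%.4f", summary@meanNaPct),
            sprintf("se_na_pct\t%.4f", summary@seNaPct),
            sprintf("mean_other_pct\t%.4f", summary@meanOtherPct),
            sprintf("se_other_pct\t%.4f", summary@seOtherPct),
            sprintf("n_raw_better\t%d", summary@nRawBetter)), sumPath)
        files <- c(files, sumPath)
    }
    invisible(files)
}

#' Read a flat key-value run configuration
#'
#' Lines of the form \code{key = value} (or \code{key<TAB>value});
#' \code{'#'} comments and blank lines ignored. Numeric-looking values are
#' converted. Used by the command-line wrapper; exposed for completeness.
#'
#' @param path Path to the config file.
#' @return Named list of settings.
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path))
        stop("no such config file '", path, "'")
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    out <- list()
    for (ln in lines) {
        kv <- strsplit(ln, "[=\t]", perl = TRUE)[[1L]]
        if (length(kv) < 2L)
            stop("malformed config line: '", ln, "'")
        key <- trimws(kv[[1L]])
        val <- trimws(paste(kv[-1L], collapse = "="))
        num <- suppressWarnings(as.numeric(val))
        out[[key]] <- if (!is.na(num)) num else val
    }
    out
}
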