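#' Construct a genus-level copy-number database
#'
#' Builds a [GCNDatabase-class] from a named vector of mean 16S rRNA gene
#' copy numbers. Genus names are trimmed and any rank prefix of the form
#' \code{"g__"} is stripped; duplicate genus names (after normalization)
#' are averaged, reflecting that a genus-level table is itself an average
#' over genomes.
#'
#' @param entries Named numeric vector, genus to mean copy number
#'   (copies per genome, all > 0). May be empty.
#' @param defaultGCN Copy number applied to genera without an entry and to
#'   the unidentified category. The conventional value, 1.8, is the mean
#'   copy number reported for bacteria without a database entry; it is an
#'   argument rather than a constant because its adequacy is exactly what
#'   this package lets you probe.
#' @param sourceLabel Free-text provenance label.
#' @return A [GCNDatabase-class].
#' @examples
#' db <- gcnDatabase(c(Bacteroides = 7, Escherichia = 7, Nitrosomonas = 1))
#' lookupGCN(db, c("Bacteroides", "Staphylococcus"))
#' @export
gcnDatabase <- function(entries = numeric(), defaultGCN = 1.8,
                        sourceLabel = "") {
    if (length(entries)) {
        names(entries) <- normalizeGenus(names(entries))
        if (anyDuplicated(names(entries)))
            entries <- vapply(split(unname(entries), names(entries)),
                              mean, numeric(1))
    }
    new("GCNDatabase", entries = entries, defaultGCN = defaultGCN,
        sourceLabel = sourceLabel)
}

#' Load a copy-number table from a delimited file
#'
#' Reads a genus/copy-number table: tab- or comma-delimited, a header line,
#' \code{'#'} comment lines ignored. Rows sharing a genus (after name
#' normalization) are averaged. Malformed rows -- non-numeric or
#' non-positive copy numbers -- raise an error naming the offending line.
#'
#' @param path Path to the table.
#' @inheritParams gcnDatabase
#' @return A [GCNDatabase-class].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("genus\tcopy_number", "Bacteroides\t7", "Vibrio\t11.5"), tf)
#' loadGCNTable(tf)
#' @export
loadGCNTable <- function(path, defaultGCN = 1.8,
                         sourceLabel = basename(path)) {
    fields <- readDelimited(path, what = "copy-number table")
    if (length(fields$rows) == 0L)
        stop("no data rows in copy-number table '", path, "'")
    genus <- character(0)
    gcn <- numeric(0)
    for (i in seq_along(fields$rows)) {
        row <- fields$rows[[i]]
        if (length(row) < 2L)
            stop(sprintf("line %d of '%s': expected 2 columns",
                         fields$lineno[i], path))
        val <- suppressWarnings(as.numeric(row[[2L]]))
        if (is.na(val))
            stop(sprintf("line %d of '%s': non-numeric copy number '%s'",
                         fields$lineno[i], path, row[[2L]]))
        if (val <= 0)
            stop(sprintf("line %d of '%s': copy number must be > 0 (got %s)",
                         fields$lineno[i], path, row[[2L]]))
        genus <- c(genus, row[[1L]])
        gcn <- c(gcn, val)
    }
    names(gcn) <- genus
    gcnDatabase(gcn, defaultGCN = defaultGCN, sourceLabel = sourceLabel)
}

#' Look up copy numbers with the default-copy-number policy
#'
#' Total over genus names: genera present in the database return their
#' stored mean copy number; genera absent from it -- including spurious
#' genera and the reserved unidentified category -- return the database's
#' default. Vectorized over \code{genus}.
#'
#' @param db A [GCNDatabase-class].
#' @param genus Character vector of genus names (normalized before lookup).
#' @return Named numeric vector of copy numbers, one per input name.
#' @examples
#' db <- gcnDatabase(c(Bacteroides = 7))
#' lookupGCN(db, c("Bacteroides", "Unknown_genus", unidentifiedToken()))
#' @export
lookupGCN <- function(db, genus) {
    stopifnot(is(db, "GCNDatabase"))
    key <- normalizeGenus(genus)
    out <- unname(db@entries[key])
    out[is.na(out)] <- db@defaultGCN
    names(out) <- genus
    out
}
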