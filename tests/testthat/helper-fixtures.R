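# Independent RSS oracle: plain named vectors, explicit loop over the
# category union. Deliberately shares no code with gcnbench::rss().
rssOracle <- function(obs, exp) {
    total <- 0
    for (g in union(names(obs), names(exp))) {
        y <- if (g %in% names(exp)) exp[[g]] else 0
        f <- if (g %in% names(obs)) obs[[g]] else 0
        total <- total + (y - f)^2
    }
    total
}

# Random profile pair with partially overlapping genus sets, as plain
# named vectors on the simplex.
randomProfilePair <- function(nGenera = 20) {
    pool <- sprintf("G%03d", seq_len(nGenera + 10))
    mk <- function() {
        genera <- sample(pool, nGenera)
        p <- stats::rexp(nGenera)
        stats::setNames(p / sum(p), genera)
    }
    list(obs = mk(), exp = mk())
}

writeTempLines <- function(lines, ext = ".tsv") {
    tf <- tempfile(fileext = ext)
    writeLines(lines, tf)
    tf
}
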