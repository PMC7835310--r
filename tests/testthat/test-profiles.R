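test_that("gcnCorrect divides each genus by its copy number", {
    ct <- countTable(c(A = 100, B = 100))
    db <- gcnDatabase(c(A = 4, B = 2))
    expect_equal(genusCounts(gcnCorrect(ct, db)), c(A = 25, B = 50))

    # the default applies to the unidentified category
    ct2 <- countTable(stats::setNames(c(90, 18), c("A", unidentifiedToken())))
    out <- genusCounts(gcnCorrect(ct2, gcnDatabase(c(A = 9), defaultGCN = 1.8)))
    expect_equal(unname(out), c(10, 10))
})

test_that("uniform copy numbers are a no-op on the relative scale", {
    ct <- countTable(c(A = 123, B = 456, C = 7))
    emptyDb <- gcnDatabase(defaultGCN = 1.8)
    expect_equal(genusAbundances(toRelative(gcnCorrect(ct, emptyDb))),
                 genusAbundances(toRelative(ct)))
})

test_that("toRelative normalizes by the table's own total", {
    expect_equal(genusAbundances(toRelative(countTable(c(A = 25, B = 50)))),
                 c(A = 1 / 3, B = 2 / 3))
    expect_equal(genusAbundances(toRelative(countTable(c(A = 7)))),
                 c(A = 1))
    expect_error(countTable(c(A = 0, B = 0)), "> 0")
    expect_error(countTable(numeric(0)), "at least one")
})

test_that("alignment uses the sorted union with zeros filled in", {
    ap <- alignProfiles(taxonProfile(c(A = 1)), taxonProfile(c(B = 1)))
    expect_identical(ap@categories, c("A", "B"))
    expect_equal(ap@observed, c(1, 0))
    expect_equal(ap@expected, c(0, 1))

    p <- taxonProfile(c(B = 0.25, A = 0.75))
    same <- alignProfiles(p, p)
    expect_identical(same@observed, same@expected)

    # mocks never contain the unidentified category; it aligns to expected 0
    obs <- taxonProfile(stats::setNames(c(0.9, 0.1),
                                        c("A", unidentifiedToken())))
    ap2 <- alignProfiles(obs, taxonProfile(c(A = 1)))
    expect_identical(ap2@categories[length(ap2@categories)],
                     unidentifiedToken())
    expect_equal(ap2@expected[length(ap2@expected)], 0)
})

test_that("rss matches hand-computed values and the loop oracle", {
    expect_equal(rss(taxonProfile(c(A = 0.6, B = 0.4)),
                     taxonProfile(c(A = 0.5, B = 0.5))), 0.02)
    p <- taxonProfile(c(A = 0.3, B = 0.7))
    expect_identical(rss(p, p), 0)
    expect_equal(rss(taxonProfile(c(A = 1)), taxonProfile(c(B = 1))), 2)

    set.seed(11)
    for (i in 1:50) {
        pair <- randomProfilePair(20)
        got <- rss(taxonProfile(pair$obs), taxonProfile(pair$exp))
        expect_equal(got, rssOracle(pair$obs, pair$exp), tolerance = 1e-12)
    }
})

test_that("rss is symmetric, bounded by [0, 2] and zero-padding invariant", {
    set.seed(12)
    for (i in 1:25) {
        pair <- randomProfilePair(15)
        a <- taxonProfile(pair$obs)
        b <- taxonProfile(pair$exp)
        r <- rss(a, b)
        expect_identical(r, rss(b, a))
        expect_gte(r, 0)
        expect_lte(r, 2)
        # inserting a category with zero abundance on both sides changes nothing
        padded <- taxonProfile(c(pair$obs, Zpad = 0))
        expect_equal(rss(padded, b), r, tolerance = 1e-15)
    }
})

test_that("correction then normalization is scale-invariant in the counts", {
    db <- gcnDatabase(c(A = 4, B = 2, C = 9))
    ct <- countTable(c(A = 10, B = 70, C = 20))
    scaled <- countTable(genusCounts(ct) * 37.5)
    expect_equal(genusAbundances(toRelative(gcnCorrect(ct, db))),
                 genusAbundances(toRelative(gcnCorrect(scaled, db))))
})

test_that("equal copy numbers everywhere give identical raw and GCN profiles", {
    db <- gcnDatabase(c(A = 3, B = 3, C = 3))
    ct <- countTable(c(A = 50, B = 30, C = 20))
    mock <- taxonProfile(c(A = 0.4, B = 0.4, C = 0.2))
    expect_equal(rss(toRelative(gcnCorrect(ct, db)), mock),
                 rss(toRelative(ct), mock))
})

test_that("profiles near the simplex are renormalized, far ones rejected", {
    p <- taxonProfile(c(A = 0.5, B = 0.4999999))  # within 1e-6
    expect_equal(sum(genusAbundances(p)), 1)
    expect_error(taxonProfile(c(A = 0.5, B = 0.4)), "sum to 1")
})
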