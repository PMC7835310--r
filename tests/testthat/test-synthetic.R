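test_that("identical seeds give identical experiments, different seeds differ", {
    a <- simulateMock(nGenera = 10, depth = 5e4, unidentifiedFrac = 0.1,
                      nSpurious = 3, spuriousMass = 0.05, seed = 99)
    b <- simulateMock(nGenera = 10, depth = 5e4, unidentifiedFrac = 0.1,
                      nSpurious = 3, spuriousMass = 0.05, seed = 99)
    expect_identical(genusCounts(observedCounts(a)),
                     genusCounts(observedCounts(b)))
    expect_identical(copyNumbers(a), copyNumbers(b))
    c <- simulateMock(nGenera = 10, depth = 5e4, unidentifiedFrac = 0.1,
                      nSpurious = 3, spuriousMass = 0.05, seed = 100)
    expect_false(identical(genusCounts(observedCounts(a)),
                           genusCounts(observedCounts(c))))
})

test_that("simulation does not disturb the caller's RNG state", {
    set.seed(42)
    before <- stats::runif(5)
    set.seed(42)
    invisible(simulateMock(nGenera = 5, depth = 1000, seed = 7))
    after <- stats::runif(5)
    expect_identical(before, after)
})

test_that("observed fractions follow abundance times copy number", {
    sim <- simulateMock(abundances = c(A = 0.5, B = 0.5),
                        copyNumbers = c(A = 4, B = 2),
                        depth = 6000, seed = 1)
    raw <- genusAbundances(toRelative(observedCounts(sim)))
    # expected weights 0.5*4 : 0.5*2 -> (2/3, 1/3); 3 binomial SDs at n=6000
    tol <- 3 * sqrt(2 / 9 / 6000)
    expect_lt(abs(raw[["A"]] - 2 / 3), tol)
    # exact correction recovers the truth up to multinomial error
    db <- gcnDatabase(copyNumbers(sim))
    expect_lt(rss(toRelative(gcnCorrect(observedCounts(sim), db)),
                  mockTruth(sim)), 1e-3)
})

test_that("the unidentified fraction is recovered with binomial error", {
    sim <- simulateMock(nGenera = 6, depth = 1e5, unidentifiedFrac = 0.3,
                        seed = 13)
    obs <- genusAbundances(toRelative(observedCounts(sim)))
    naObs <- obs[[unidentifiedToken()]]
    expect_lt(abs(naObs - 0.3), 3 * sqrt(0.3 * 0.7 / 1e5))
})

test_that("spurious genera carry their stated mass and read as foreign", {
    sim <- simulateMock(nGenera = 5, depth = 1e5, nSpurious = 4,
                        spuriousMass = 0.08, seed = 21)
    expect_true(all(sprintf("Spurious%02d", 1:4) %in% names(copyNumbers(sim))))
    raw <- toRelative(observedCounts(sim))
    mis <- misidentification(raw, mockTruth(sim))
    expect_lt(abs(mis$otherFrac - 0.08), 3 * sqrt(0.08 * 0.92 / 1e5))
    # the evaluation path treats them with the default copy number:
    # a database holding only the true genera still evaluates cleanly
    db <- gcnDatabase(copyNumbers(sim)[names(genusAbundances(mockTruth(sim)))])
    ev <- evaluateCommunity(observedCounts(sim), mockTruth(sim), db)
    expect_gt(ev@otherFrac, 0)
})

test_that("GCN-corrected profiles converge to truth as depth grows", {
    sim <- simulateMock(nGenera = 12, depth = 1e6, seed = 3)
    db <- gcnDatabase(copyNumbers(sim))
    ev <- evaluateCommunity(observedCounts(sim), mockTruth(sim), db)
    expect_lt(ev@rssGCN, 1e-4)
    expect_gt(ev@rssRaw, ev@rssGCN)  # copy numbers are non-constant here
})

test_that("raw misfit grows with the spread of copy numbers", {
    spreads <- c(0, 1, 2, 3)
    shape <- c(-1, -1 / 3, 1 / 3, 1)
    meanRss <- vapply(spreads, function(s) {
        cn <- stats::setNames(4 + s * shape, sprintf("Genus%02d", 1:4))
        mean(vapply(1:30, function(rep) {
            sim <- simulateMock(
                abundances = stats::setNames(rep(0.25, 4), names(cn)),
                copyNumbers = cn, depth = 2e4, seed = 1000 + rep)
            rss(toRelative(observedCounts(sim)), mockTruth(sim))
        }, numeric(1)))
    }, numeric(1))
    expect_true(all(diff(meanRss) > 0))
})

test_that("the high-copy-number scenario penalizes the 1.8 default", {
    sim <- scenarioMock19(depth = 1e5, seed = 7)
    expect_equal(mean(copyNumbers(sim)), 6.6)
    db <- gcnDatabase(copyNumbers(sim), defaultGCN = 1.8)
    ev <- evaluateCommunity(observedCounts(sim), mockTruth(sim), db)
    expect_identical(ev@bestFit, "raw")
    expect_gt(ev@rssGCN, ev@rssRaw)
    # the remedy: a default at the true mean copy number deflates the
    # unidentified category again
    db66 <- gcnDatabase(copyNumbers(sim), defaultGCN = 6.6)
    ev66 <- evaluateCommunity(observedCounts(sim), mockTruth(sim), db66)
    expect_lte(ev66@rssGCN, ev@rssGCN)
    # with no unidentified mass the correction is essentially exact
    clean <- simulateMock(abundances = genusAbundances(mockTruth(sim)),
                          copyNumbers = copyNumbers(sim),
                          depth = 1e5, seed = 7)
    evc <- evaluateCommunity(observedCounts(clean), mockTruth(clean),
                             gcnDatabase(copyNumbers(clean)))
    expect_identical(evc@bestFit, "gcn")
})

test_that("degenerate simulation requests are rejected", {
    expect_error(simulateMock(nGenera = 3, depth = 100), "seed")
    expect_error(simulateMock(nGenera = 3, depth = 100,
                              unidentifiedFrac = 0.6, nSpurious = 1,
                              spuriousMass = 0.5, seed = 1), "room")
    expect_error(simulateMock(abundances = c(A = 1),
                              copyNumbers = c(B = 2), depth = 10, seed = 1),
                 "exactly the true genera")
})
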