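test_that("evaluateCommunity is exact when correction undoes the bias", {
    # counts constructed so that dividing by the copy numbers recovers the mock
    ct <- countTable(c(A = 100, B = 100), "constructed")
    mock <- taxonProfile(c(A = 1 / 3, B = 2 / 3))
    ev <- evaluateCommunity(ct, mock, gcnDatabase(c(A = 4, B = 2)))
    expect_equal(ev@rssGCN, 0, tolerance = 1e-12)
    expect_equal(ev@rssRaw, 2 * (1 / 6)^2)
    expect_identical(ev@bestFit, "gcn")
    expect_identical(ev@richnessMock, 2L)
    expect_false(ev@excluded)
})

test_that("an RSS tie goes to the raw pipeline", {
    ct <- countTable(c(A = 40, B = 60))
    mock <- taxonProfile(c(A = 0.4, B = 0.6))
    ev <- evaluateCommunity(ct, mock, gcnDatabase(c(A = 2, B = 2)))
    expect_identical(ev@rssRaw, ev@rssGCN)
    expect_identical(ev@bestFit, "raw")
})

test_that("evaluation recovers simulator ground truth at depth", {
    sim <- simulateMock(nGenera = 8, depth = 1e5, seed = 41)
    db <- gcnDatabase(copyNumbers(sim))
    ev <- evaluateCommunity(observedCounts(sim), mockTruth(sim), db)
    expect_identical(ev@richnessMock, 8L)
    expect_identical(ev@richnessRaw, 8L)
    expect_identical(ev@naFrac, 0)
    expect_identical(ev@otherFrac, 0)
    expect_lt(ev@rssGCN, 1e-3)
    expect_identical(ev@shannonMock,
                     shannonDiversity(mockTruth(sim)))
})

test_that("flagBestFit reproduces published best-fit calls and the tie rule", {
    expect_identical(flagBestFit(0.5198, 0.5258), "raw")
    expect_identical(flagBestFit(0.5245, 0.4991), "gcn")
    expect_identical(flagBestFit(0.3, 0.3), "raw")
    expect_identical(flagBestFit(c(1, 2), c(2, 1)), c("raw", "gcn"))
})

test_that("the packaged benchmark ships all eleven communities verbatim", {
    ref <- referenceEvaluations()
    expect_length(ref, 11L)
    expect_identical(ref[["Mock-19"]]@rssGCN, 1.1353)
    expect_identical(ref[["Mock-19"]]@naFrac, 0.3074)
    expect_true(ref[["Mock-12"]]@excluded)
    expect_identical(sum(vapply(ref, methods::slot, logical(1), "excluded")),
                     1L)
    tab <- evaluationTable(ref)
    expect_identical(nrow(tab), 11L)
    expect_identical(tab$community_id[1], "Mock-12")
})

test_that("cohort aggregation is permutation-invariant and needs n >= 2", {
    ref <- referenceEvaluations()
    s1 <- aggregateCohort(ref)
    set.seed(5)
    s2 <- aggregateCohort(sample(ref))
    for (sl in slotNames("CohortSummary"))
        expect_identical(methods::slot(s1, sl), methods::slot(s2, sl))
    expect_identical(s1@n, 10L)

    # two identical results: zero SEs
    ev <- evaluateCommunity(countTable(c(A = 100, B = 100)),
                            taxonProfile(c(A = 1 / 3, B = 2 / 3)),
                            gcnDatabase(c(A = 4, B = 2)))
    twin <- aggregateCohort(list(ev, ev))
    expect_identical(twin@seRssDiffPct, 0)
    expect_identical(twin@seNaPct, 0)

    expect_error(aggregateCohort(list(ev)), "at least 2")
})
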