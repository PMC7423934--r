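make_rep_set <- function() {
    m <- matrix(c(3, 4, 5, 2,   # P1 across runs
                  0, 1, 2, 9),  # P2
                nrow = 2, byrow = TRUE,
                dimnames = list(c("P1", "P2"),
                                c("S1.r1", "S1.r2", "S1.r3", "S2.r1")))
    SpectralCountSet(m, sample = c("S1", "S1", "S1", "S2"),
                     replicate = c("r1", "r2", "r3", "r1"))
}

test_that("replicate aggregation sums or mean-rounds per sample", {
    scs <- make_rep_set()
    agg <- aggregateReplicates(scs, "sum")
    expect_equal(counts(agg)["P1", "S1"], 12)        # 3 + 4 + 5
    expect_equal(counts(agg)["P2", "S2"], 9)
    # sum conserves the per-sample total spectral counts
    expect_equal(sum(counts(agg)[, "S1"]), sum(counts(scs)[, 1:3]))

    mr <- aggregateReplicates(scs, "mean_round")
    expect_equal(counts(mr)["P1", "S1"], 4)          # 12 / 3
    expect_equal(counts(mr)["P2", "S1"], 1)          # 3 / 3
    # half-up rounding: mean 1.5 -> 2
    m2 <- SpectralCountSet(matrix(c(1, 2), 1, 2,
                                  dimnames = list("P1", c("S.r1", "S.r2"))),
                           sample = c("S", "S"))
    expect_equal(counts(aggregateReplicates(m2, "mean_round"))[1, 1], 2)

    # single replicate per sample: output equals input
    one <- SpectralCountSet(matrix(c(5, 7), 1, 2,
                                   dimnames = list("P1", c("S1", "S2"))))
    expect_identical(counts(aggregateReplicates(one, "sum")), counts(one))
    expect_error(aggregateReplicates(scs, "median"))
})

test_that("normalization obeys its column contracts", {
    m <- matrix(c(2, 2, 4, 1, 0, 1), 3, 2,
                dimnames = list(c("P1", "P2", "P3"), c("S1", "S2")))
    scs <- SpectralCountSet(m)
    tc <- normalizeCounts(scs, "total_count")
    expect_equal(tc@.Data[, "S1"], c(P1 = 0.25, P2 = 0.25, P3 = 0.5))
    expect_equal(unname(colSums(tc@.Data)), c(1, 1), tolerance = 1e-12)
    expect_identical(normMethod(tc), "total_count")

    lt <- normalizeCounts(scs, "log2_total")
    expect_equal(lt@.Data["P3", "S1"], log2(1 + 1e4 * 0.5))

    zero <- SpectralCountSet(matrix(c(1, 0), 1, 2,
                                    dimnames = list("P1", c("S1", "S2"))))
    expect_error(normalizeCounts(zero, "total_count"), "S2")
})

test_that("characteristic proteins follow the more-than-three-samples rule", {
    # 5 AIS samples; P1 present in 4, P2 in 3, P3 in all
    m <- rbind(P1 = c(1, 1, 1, 1, 0, 1, 1),
               P2 = c(1, 1, 1, 0, 0, 0, 0),
               P3 = c(2, 5, 1, 3, 9, 1, 1))
    colnames(m) <- sprintf("S%d", 1:7)
    scs <- SpectralCountSet(m)
    d <- GroupDesign(colnames(m), rep(c("AIS", "MIA"), c(5, 2)))
    sets <- suppressWarnings(characteristicProteins(scs, d, minSamples = 4))
    expect_true("P1" %in% sets$AIS)
    expect_false("P2" %in% sets$AIS)        # 3 of 5 is not more than three
    expect_true("P3" %in% sets$AIS)
    # group smaller than minSamples yields an empty set with a warning
    expect_warning(s2 <- characteristicProteins(scs, d, minSamples = 4),
                   "MIA")
    expect_identical(s2$MIA, character(0))

    # protein positive in all samples of all groups is in every set
    sets2 <- characteristicProteins(scs, d, minSamples = 2)
    expect_true(all(vapply(sets2, function(s) "P3" %in% s, logical(1))))
})

test_that("characteristic sets shrink monotonically in minSamples", {
    set.seed(42)
    m <- matrix(rpois(50 * 7, 0.8), 50, 7,
                dimnames = list(sprintf("P%02d", 1:50), sprintf("S%d", 1:7)))
    scs <- SpectralCountSet(m)
    d <- GroupDesign(colnames(m), rep(c("A", "B"), c(4, 3)))
    prev <- NULL
    for (k in 1:3) {
        sets <- characteristicProteins(scs, d, minSamples = k)
        if (!is.null(prev))
            for (g in names(sets))
                expect_true(all(sets[[g]] %in% prev[[g]]))
        prev <- sets
    }
})

test_that("overlap counts partition the union of per-group sets", {
    sets <- list(A = c("P1", "P2", "P3"), B = c("P2", "P3", "P4"))
    oc <- overlapCounts(sets)
    expect_equal(sum(oc$n), 4)  # union size
    expect_equal(oc$n[oc$groups == "A&B"], 2)
})
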