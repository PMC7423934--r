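test_that("contingency tables are protein counts vs remaining counts", {
    m <- rbind(P1 = c(4, 6, 0, 0), P2 = c(40, 50, 60, 40))
    colnames(m) <- sprintf("S%d", 1:4)
    scs <- SpectralCountSet(m)
    d <- GroupDesign(colnames(m), c("A", "A", "B", "B"))
    tab <- buildContingency(scs, "P1", d, "A", "B")
    expect_equal(unname(tab), matrix(c(10, 90, 0, 100), 2))
    # absent-everywhere protein gives a zero top row
    m2 <- rbind(P1 = c(0, 0, 0, 0), P2 = c(50, 50, 50, 50))
    colnames(m2) <- colnames(m)
    tab2 <- buildContingency(SpectralCountSet(m2), "P1", d, "A", "B")
    expect_equal(unname(tab2[1, ]), c(0, 0))
    expect_error(buildContingency(scs, "PX", d, "A", "B"), "unknown protein")
    expect_error(buildContingency(scs, "P1", d, "A", "C"), "unknown group")
})

test_that("G statistic matches the independent formula oracle", {
    # proportional table: exactly zero
    g0 <- gStatistic(matrix(c(5, 50, 5, 50), 2))
    expect_identical(g0$G, 0)
    expect_identical(g0$p, 1)

    # frozen hand-computed values for [[10,0],[90,100]]
    g <- gStatistic(matrix(c(10, 90, 0, 100), 2))
    expect_equal(g$G, 14.3895, tolerance = 1e-4)
    expect_equal(g$q_williams, 1.050132, tolerance = 1e-6)
    expect_equal(g$G_adj, 13.70257, tolerance = 1e-5)
    expect_equal(g$p, 2.141611e-4, tolerance = 1e-4)

    # random tables agree with the oracle to high precision
    set.seed(9)
    for (i in 1:50) {
        tab <- matrix(rpois(4, 20) + 1, 2)
        g <- gStatistic(tab)
        o <- oracle_g(tab)
        expect_equal(g$G, o$G, tolerance = 1e-12)
        expect_equal(g$q_williams, o$q, tolerance = 1e-12)
        expect_equal(g$p, o$p, tolerance = 1e-12)
    }

    # zero row margin short-circuits to the degenerate convention
    gz <- gStatistic(matrix(c(0, 90, 0, 100), 2))
    expect_identical(gz$G, 0)
    expect_identical(gz$p, 1)
    expect_error(gStatistic(matrix(c(-1, 2, 3, 4), 2)), "negative")
})

test_that("G is invariant under transposition and row/column swaps, and Williams only shrinks", {
    set.seed(21)
    for (i in 1:40) {
        tab <- matrix(rpois(4, 15), 2)
        if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
        g <- gStatistic(tab)
        expect_equal(g$G, gStatistic(t(tab))$G, tolerance = 1e-12)
        expect_equal(g$G, gStatistic(tab[2:1, 2:1])$G, tolerance = 1e-12)
        expect_gte(g$q_williams, 1)
        expect_lte(g$G_adj, g$G + 1e-12)
        if (g$G > 0)  # correction strictly enlarges p
            expect_gt(g$p, pchisq(g$G, 1, lower.tail = FALSE))
    }
})

test_that("vectorized pairwise G agrees with the scalar implementation", {
    set.seed(5)
    f11 <- rpois(30, 8); f12 <- rpois(30, 8)
    tA <- sum(f11) + 500; tB <- sum(f12) + 500
    v <- lepinet:::.g_stat_vec(f11, f12, tA, tB)
    for (i in seq_along(f11)) {
        s <- gStatistic(matrix(c(f11[i], tA - f11[i], f12[i], tB - f12[i]), 2))
        expect_equal(v$G[i], s$G, tolerance = 1e-12)
        expect_equal(v$p[i], s$p, tolerance = 1e-12)
    }
})

test_that("BH adjustment is exact step-up and rejects bad input", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.5)),
                 c(0.04, 0.04, 0.04, 0.5))
    expect_equal(bhAdjust(1), 1)
    expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
    set.seed(3)
    p <- runif(200)
    expect_equal(bhAdjust(p), oracle_bh(p), tolerance = 1e-12)
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
    expect_error(bhAdjust(numeric(0)), "empty")
})

test_that("relative abundance is the group share of across-group means", {
    m <- rbind(P1 = c(6, 0, 2, 0, 0, 0),  # means 3, 1, 0
               P2 = c(1, 1, 1, 1, 1, 1),  # equal means
               P3 = c(4, 4, 0, 0, 0, 0))  # only in A
    colnames(m) <- sprintf("S%d", 1:6)
    nm <- normalizeCounts(SpectralCountSet(m), "none")
    d <- GroupDesign(colnames(m), rep(c("A", "B", "C"), each = 2))
    sh <- relativeAbundance(nm, d)
    expect_equal(unname(sh["P1", ]), c(0.75, 0.25, 0))
    expect_equal(unname(sh["P2", ]), rep(1 / 3, 3))
    expect_equal(unname(sh["P3", ]), c(1, 0, 0))
    expect_equal(unname(rowSums(sh)), rep(1, 3))
    expect_error(relativeAbundance(nm, d, "PX"), "unknown protein")
})

test_that("the three-part rule flags planted group-specific proteins and nothing flat", {
    spec <- simSpec(nProteins = 400, seed = 303, noise = "poisson",
                    differential = list(list(n = 5, group = "AIS",
                                             fold = 20)))
    sim <- simulateCounts(spec)
    agg <- aggregateReplicates(sim$counts)
    res <- significantProteins(agg, sim$design)
    gs <- groupStats(res)
    planted <- sim$truth$differential$protein
    hits <- gs$protein[gs$group == "AIS" & gs$significant]
    expect_gte(length(intersect(planted, hits)), 4)  # >= 4 of 5 at 20-fold

    # flat protein: identical counts in all samples is never significant
    m <- rbind(PF = rep(7, 6), PO = c(9, 1, 5, 5, 1, 9))
    colnames(m) <- sprintf("S%d", 1:6)
    dd <- GroupDesign(colnames(m), rep(c("A", "B"), each = 3))
    r2 <- significantProteins(SpectralCountSet(m), dd)
    expect_false(any(groupStats(r2)$significant[groupStats(r2)$protein == "PF"]))
})

test_that("presence below 60 percent fails criterion (a) despite huge counts", {
    # P1 in 2 of 5 samples of A (40%) with huge counts
    m <- rbind(P1 = c(900, 900, 0, 0, 0, 0, 0, 0, 0, 0),
               P2 = c(10, 12, 11, 9, 10, 10, 12, 9, 11, 10),
               P3 = c(5, 5, 5, 5, 5, 500, 500, 500, 500, 500))
    colnames(m) <- sprintf("S%02d", 1:10)
    d <- GroupDesign(colnames(m), rep(c("A", "B"), each = 5))
    res <- significantProteins(SpectralCountSet(m), d)
    gs <- groupStats(res)
    r1 <- gs[gs$protein == "P1" & gs$group == "A", ]
    expect_equal(r1$presence_fraction, 0.4)
    expect_false(r1$significant)
    expect_error(significantProteins(
        SpectralCountSet(m),
        GroupDesign(colnames(m), rep("A", 10))), ">= 2 groups")
})
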