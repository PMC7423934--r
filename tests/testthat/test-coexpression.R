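test_that("correlation matrix is Pearson with guarded degeneracies", {
    m <- rbind(P1 = c(1, 2, 3), P2 = c(2, 4, 6), P3 = c(3, 2, 1))
    colnames(m) <- c("S1", "S2", "S3")
    r <- pearsonMatrix(m)
    expect_equal(r["P1", "P2"], 1)
    expect_equal(r["P1", "P3"], -1)
    expect_equal(unname(diag(r)), rep(1, 3))
    expect_error(pearsonMatrix(rbind(P1 = c(1, 1, 1), P2 = c(1, 2, 3))),
                 "zero-variance.*P1")
    expect_error(pearsonMatrix(m[, 1:2]), ">= 3 samples")

    # independent long profiles: pairwise r concentrates near zero
    set.seed(1)
    big <- matrix(rnorm(20 * 1000), 20)
    rownames(big) <- sprintf("P%02d", 1:20)
    rb <- pearsonMatrix(big)
    off <- rb[upper.tri(rb)]
    expect_lt(max(abs(off)), 0.15)
    expect_lt(abs(mean(off)), 0.01)
})

test_that("soft-thresholded adjacency transforms are exact", {
    r <- matrix(c(1, 0.8, 0.8, 1), 2)
    expect_equal(adjacencyFromCorrelation(r, 10, "unsigned")[1, 2],
                 0.8^10)
    r1 <- matrix(c(1, 1, 1, 1), 2)
    expect_equal(adjacencyFromCorrelation(r1, 7, "signed")[1, 2], 1)
    rm1 <- matrix(c(1, -1, -1, 1), 2)
    expect_equal(adjacencyFromCorrelation(rm1, 7, "signed")[1, 2], 0)
    # the reversed transform connects anticorrelated pairs instead
    expect_equal(adjacencyFromCorrelation(rm1, 3, "dissimilarity")[1, 2], 1)
    expect_equal(unname(diag(adjacencyFromCorrelation(r, 10, "signed"))),
                 c(1, 1))
    expect_error(adjacencyFromCorrelation(r, 10, "magic"))
})

test_that("scale-free fit index is ~1 on an exact power law and NA when degenerate", {
    # degree sequence with frequency exactly proportional to k^-1 on a
    # log-spaced grid: the binned log-log regression must be a perfect line
    vals <- 10^(seq(0.2, 2, by = 0.2))
    k <- rep(vals, times = round(1000 / vals))
    expect_gte(lepinet:::.scale_free_rsq(k, nBins = 10), 0.99)
    expect_true(is.na(lepinet:::.scale_free_rsq(rep(5, 100))))
})

test_that("soft threshold recommendation follows the stated rule", {
    sim <- simulateCounts(simSpec(
        nProteins = 120, seed = 17,
        modules = list(list(size = 40, group = NA, loading = 0.9),
                       list(size = 30, group = "LPA", loading = 0.8))))
    nm <- normalizeCounts(aggregateReplicates(sim$counts), "log2_total")
    fit <- softThresholdFit(nm, powers = c(2, 4, 6, 8, 10, 12))
    rec <- attr(fit, "recommended")
    expect_true(rec %in% fit$power)
    ok <- which(!is.na(fit$sft_rsq) & fit$sft_rsq >= 0.8)
    if (length(ok)) expect_identical(rec, fit$power[ok[1]])
    else expect_identical(rec, fit$power[which.max(fit$sft_rsq)])
    # mean connectivity decreases with beta
    expect_true(all(diff(fit$mean_k) < 0))
})

test_that("TOM matches its closed forms and stays in [0,1]", {
    # complete unit-weight triangle: all-ones
    ones <- matrix(1, 3, 3)
    expect_equal(tomSimilarity(ones), matrix(1, 3, 3))
    # star a12 = a13 = 0.5, a23 = 0: TOM_12 = (0 + 0.5)/(0.5 + 1 - 0.5)
    a <- diag(3)
    a[1, 2] <- a[2, 1] <- 0.5
    a[1, 3] <- a[3, 1] <- 0.5
    expect_equal(tomSimilarity(a)[1, 2], 0.5)
    # isolated pair: zero denominator convention
    expect_equal(tomSimilarity(diag(2))[1, 2], 0)
    expect_error(tomSimilarity(matrix(c(1, 0.2, 0.4, 1), 2)),
                 "not symmetric")
    expect_error(tomSimilarity(matrix(c(1, 2, 2, 1), 2)), "\\[0, 1\\]")

    set.seed(12)
    r <- cor(matrix(rnorm(15 * 40), 15))
    tt <- tomSimilarity(adjacencyFromCorrelation(r, 6, "signed"))
    expect_true(all(tt >= 0 & tt <= 1))
    expect_true(isSymmetric(unname(tt), tol = 1e-12))
    expect_equal(unname(diag(tt)), rep(1, 40))
})

test_that("average-linkage trees are deterministic and merge blocks first", {
    d2 <- matrix(c(0, 0.3, 0.3, 0), 2,
                 dimnames = list(c("a", "b"), c("a", "b")))
    hc2 <- hclustAverage(d2)
    expect_equal(hc2$height, 0.3)

    d <- block_diss(c(5, 5))
    hc <- hclustAverage(d)
    # first 8 merges happen inside the two tight blocks, near zero
    expect_true(all(hc$height[1:8] < 0.1))

    # duplicate distances: repeated runs give the identical tree
    dd <- matrix(0.5, 6, 6); diag(dd) <- 0
    dimnames(dd) <- list(letters[1:6], letters[1:6])
    expect_identical(hclustAverage(dd)$merge, hclustAverage(dd)$merge)
    dn <- d; dn[1, 2] <- NA; dn[2, 1] <- NA
    expect_error(hclustAverage(dn), "NA")
})

test_that("eigen-protein is the intramodular connectivity argmax with id tie-break", {
    a <- diag(4)
    a[1, 2:4] <- a[2:4, 1] <- 1       # P1 connected to everyone
    a[2, 3] <- a[3, 2] <- 0.1
    dimnames(a) <- list(paste0("P", 1:4), paste0("P", 1:4))
    lab <- structure(c(1L, 1L, 1L, 1L), names = paste0("P", 1:4))
    expect_identical(unname(eigenProteinOf(a, lab)), "P1")

    # singleton module
    lab2 <- structure(c(1L, 2L, 1L, 1L), names = paste0("P", 1:4))
    expect_identical(unname(eigenProteinOf(a, lab2)["2"]), "P2")

    # exact tie between two equally connected proteins: smaller id wins
    at <- matrix(0.5, 2, 2); diag(at) <- 1
    dimnames(at) <- list(c("Pb", "Pa"), c("Pb", "Pa"))
    labt <- structure(c(1L, 1L), names = c("Pb", "Pa"))
    expect_identical(unname(eigenProteinOf(at, labt)), "Pa")
})

test_that("module-trait correlation has exact endpoints and honest flags", {
    tv_design <- GroupDesign(sprintf("S%d", 1:8),
                             rep(c("A", "B"), each = 4))
    # profile equal to the A trait vector
    m <- rbind(PH = c(1, 1, 1, 1, 0, 0, 0, 0),
               PO = c(1, -1, 1, -1, 1, -1, 1, -1))
    colnames(m) <- sprintf("S%d", 1:8)
    ts <- moduleTraitCorrelation(m, c(`1` = "PH", `2` = "PO"), tv_design)
    r1 <- ts[ts$module == "1" & ts$trait == "A", ]
    expect_equal(r1$r, 1)
    expect_lt(r1$p, 1e-6)
    expect_true(r1$high_cor)
    # orthogonal profile in a balanced design: r = 0, p = 1
    r2 <- ts[ts$module == "2" & ts$trait == "A", ]
    expect_equal(r2$r, 0)
    expect_equal(r2$p, 1)
    # constant profile propagates NA
    mc <- rbind(PC = rep(2, 8)); colnames(mc) <- sprintf("S%d", 1:8)
    tc <- moduleTraitCorrelation(mc, c(`1` = "PC"), tv_design)
    expect_true(all(is.na(tc$r)))
})

test_that("a trait-driven module is flagged at |r| > 0.5 and q < 0.05", {
    sim <- simulateCounts(simSpec(
        nProteins = 600, seed = 77,
        modules = list(list(size = 30, group = "LPA", loading = 0.9),
                       list(size = 30, group = NA, loading = 0.9))))
    nm <- normalizeCounts(aggregateReplicates(sim$counts), "log2_total")
    fit <- suppressMessages(buildCoexprModel(nm, sim$design))
    ts <- traitStats(fit)
    lpa <- ts[ts$trait == "LPA", ]
    best <- lpa[which.max(abs(lpa$r)), ]
    expect_true(best$high_cor)
    expect_true(best$significant)
    # the top-|r| module for LPA carries the planted trait-linked proteins
    mem <- names(moduleLabels(fit))[moduleLabels(fit) == best$module]
    truth_mem <- names(sim$truth$moduleLabels)[sim$truth$moduleLabels == 1]
    expect_gt(length(intersect(mem, truth_mem)) / length(truth_mem), 0.8)
})

test_that("the pipeline is deterministic for identical input", {
    sim <- simulateCounts(simSpec(nProteins = 80, seed = 5,
        modules = list(list(size = 20, group = "MIA", loading = 0.9))))
    nm <- normalizeCounts(aggregateReplicates(sim$counts), "log2_total")
    f1 <- buildCoexprModel(nm, sim$design, minModuleSize = 5)
    f2 <- buildCoexprModel(nm, sim$design, minModuleSize = 5)
    expect_identical(moduleLabels(f1), moduleLabels(f2))
    expect_identical(traitStats(f1), traitStats(f2))
})
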