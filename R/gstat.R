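## Pairwise G-statistics on 2x2 spectral-count tables with Williams'
## continuity correction, BH control, and the three-part group-significance
## rule (presence >= 60%, relative abundance > 50%, q < 0.05 in both
## pairwise comparisons).

#' Build the 2x2 contingency table for one protein and one group pair
#'
#' Row 1 holds the protein's summed spectral counts in groups A and B; row
#' 2 the remaining counts (group total minus the protein), the canonical
#' construction for spectral-count G-tests.
#'
#' @param x aggregated [SpectralCountSet-class].
#' @param protein protein id.
#' @param design a [GroupDesign-class].
#' @param groupA,groupB group labels to compare.
#' @return 2x2 numeric matrix with dimnames
#'   \code{list(c(protein, "other"), c(groupA, groupB))}.
#' @export
buildContingency <- function(x, protein, design, groupA, groupB) {
    m <- counts(x)
    .check_design(m, design)
    if (!protein %in% rownames(m)) stop("unknown protein: ", protein)
    asg <- groupAssignments(design)
    for (g in c(groupA, groupB))
        if (!g %in% groupLevels(design)) stop("unknown group: ", g)
    sA <- names(asg)[asg == groupA]
    sB <- names(asg)[asg == groupB]
    f11 <- sum(m[protein, sA]); f12 <- sum(m[protein, sB])
    tA <- sum(m[, sA]); tB <- sum(m[, sB])
    tab <- matrix(c(f11, tA - f11, f12, tB - f12), 2L, 2L,
                  dimnames = list(c(protein, "other"), c(groupA, groupB)))
    if (sum(tab) == 0) stop("total count is zero for groups ",
                            groupA, "/", groupB)
    tab
}

#' Williams-corrected G statistic for a 2x2 table
#'
#' Log-likelihood-ratio statistic G = 2 sum O log(O/E) with expecteds from
#' the margins and the convention 0 log(0/E) = 0, divided by Williams'
#' correction q = 1 + (N/R1 + N/R2 - 1)(N/C1 + N/C2 - 1)/(6N). The
#' correction shrinks G, so it always enlarges p, which makes the test
#' usable on tables with small counts including zeros. A zero row or
#' column margin makes the table degenerate: G = 0, p = 1.
#'
#' @param tab 2x2 non-negative numeric matrix.
#' @return list with \code{G}, \code{q_williams}, \code{G_adj}, \code{p}
#'   (upper-tail chi-square, 1 df, on \code{G_adj}).
#' @examples
#' gStatistic(matrix(c(10, 90, 0, 100), 2))
#' @export
gStatistic <- function(tab) {
    tab <- as.matrix(tab)
    stopifnot(identical(dim(tab), c(2L, 2L)))
    if (any(tab < 0)) stop("negative cell count")
    R <- rowSums(tab); C <- colSums(tab); N <- sum(tab)
    if (N == 0) stop("empty table")
    if (any(R == 0) || any(C == 0))
        return(list(G = 0, q_williams = 1, G_adj = 0, p = 1))
    E <- outer(R, C) / N
    terms <- ifelse(tab > 0, tab * log(tab / E), 0)
    G <- 2 * sum(terms)
    G <- max(G, 0)  # guard tiny negative rounding
    q <- 1 + (N / R[1] + N / R[2] - 1) * (N / C[1] + N / C[2] - 1) / (6 * N)
    G_adj <- G / q
    list(G = G, q_williams = unname(q), G_adj = G_adj,
         p = stats::pchisq(G_adj, df = 1, lower.tail = FALSE))
}

## vectorized G over many proteins for one group pair: f11, f12 are
## per-protein counts, tA/tB the group totals. Same formulas as
## gStatistic(), evaluated column-wise.
.g_stat_vec <- function(f11, f12, tA, tB) {
    f21 <- tA - f11; f22 <- tB - f12
    R1 <- f11 + f12; R2 <- f21 + f22
    C1 <- tA; C2 <- tB
    N <- C1 + C2
    xlx <- function(o, e) ifelse(o > 0, o * log(o / e), 0)
    E11 <- R1 * C1 / N; E12 <- R1 * C2 / N
    E21 <- R2 * C1 / N; E22 <- R2 * C2 / N
    G <- 2 * (xlx(f11, E11) + xlx(f12, E12) + xlx(f21, E21) + xlx(f22, E22))
    G <- pmax(G, 0)
    q <- 1 + (N / R1 + N / R2 - 1) * (N / C1 + N / C2 - 1) / (6 * N)
    degen <- R1 == 0 | R2 == 0 | C1 == 0 | C2 == 0
    G[degen] <- 0
    q[degen] <- 1
    G_adj <- G / q
    p <- stats::pchisq(G_adj, df = 1, lower.tail = FALSE)
    p[degen] <- 1
    data.frame(G = G, q_williams = q, G_adj = G_adj, p = p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validates the inputs then applies the standard BH step-up procedure
#' (\code{stats::p.adjust}), returning q-values in input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return q-values, same length and order.
#' @export
bhAdjust <- function(p) {
    if (length(p) == 0L) stop("empty p-value vector")
    if (any(is.na(p)) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Per-group relative abundance of proteins
#'
#' The share of group g for protein i is the mean normalized abundance of i
#' in g divided by the sum of those group means over all groups; shares sum
#' to 1 across groups. Proteins with zero abundance everywhere get NA
#' shares (flagged undefined).
#'
#' @param nm a [NormalizedMatrix-class].
#' @param design a [GroupDesign-class].
#' @param proteins protein ids (default all rows).
#' @return numeric matrix, proteins x groups.
#' @export
relativeAbundance <- function(nm, design, proteins = rownames(nm)) {
    m <- nm@.Data
    .check_design(m, design)
    missing <- setdiff(proteins, rownames(m))
    if (length(missing)) stop("unknown protein(s): ",
                              paste(missing, collapse = ", "))
    asg <- groupAssignments(design)
    gm <- vapply(groupLevels(design), function(g)
        rowMeans(m[proteins, names(asg)[asg == g], drop = FALSE]),
        numeric(length(proteins)))
    if (length(proteins) == 1L)
        gm <- matrix(gm, 1L, dimnames = list(proteins, groupLevels(design)))
    tot <- rowSums(gm)
    share <- sweep(gm, 1L, tot, "/")
    share[tot == 0, ] <- NA_real_
    rownames(share) <- proteins
    share
}

#' Pairwise G-statistic differential analysis with group significance
#'
#' Runs the Williams-corrected G-test for every protein and every pair of
#' groups, adjusts p-values by BH, and flags a protein significant to group
#' g when (a) it is observed (SpC > 0) in at least \code{presenceMin} of
#' g's samples, (b) its relative abundance share for g exceeds
#' \code{shareMin}, and (c) its BH q-value is below \code{alpha} in both
#' pairwise comparisons of g against every other group.
#'
#' @param x aggregated [SpectralCountSet-class] of raw integer counts (the
#'   G-test is count-based; normalization enters only through the relative
#'   abundance criterion).
#' @param design a [GroupDesign-class] with >= 2 usable groups.
#' @param alpha BH q-value threshold (default 0.05).
#' @param presenceMin minimum fraction of group samples with SpC > 0
#'   (default 0.6).
#' @param shareMin minimum relative abundance share (default 0.5, strict
#'   >).
#' @param bhFamily \code{"pooled"} adjusts all (protein, pair) p-values as
#'   one family (default); \code{"per_pair"} adjusts within each group
#'   pair.
#' @param normalization method used for the relative-abundance shares.
#' @return a [DiffResult-class].
#' @export
significantProteins <- function(x, design, alpha = 0.05, presenceMin = 0.6,
                                shareMin = 0.5,
                                bhFamily = c("pooled", "per_pair"),
                                normalization = "total_count") {
    bhFamily <- match.arg(bhFamily)
    m <- counts(x)
    .check_design(m, design)
    sz <- groupSizes(design)
    lv <- names(sz)[sz >= 2]
    if (length(lv) < 2)
        stop("pairwise analysis needs >= 2 groups with >= 2 samples")
    asg <- groupAssignments(design)
    gsamp <- lapply(lv, function(g) names(asg)[asg == g])
    names(gsamp) <- lv
    gcount <- vapply(gsamp, function(s)
        rowSums(m[, s, drop = FALSE]), numeric(nrow(m)))
    gtotal <- colSums(gcount)

    pairs <- utils::combn(lv, 2L)
    pair_list <- vector("list", ncol(pairs))
    for (k in seq_len(ncol(pairs))) {
        a <- pairs[1L, k]; b <- pairs[2L, k]
        st <- .g_stat_vec(gcount[, a], gcount[, b], gtotal[a], gtotal[b])
        pair_list[[k]] <- data.frame(protein = rownames(m), groupA = a,
                                     groupB = b, st,
                                     stringsAsFactors = FALSE)
    }
    pairStats <- do.call(rbind, pair_list)
    pairStats$q <- if (bhFamily == "pooled") bhAdjust(pairStats$p)
                   else stats::ave(pairStats$p,
                                   paste(pairStats$groupA, pairStats$groupB),
                                   FUN = bhAdjust)

    nmx <- normalizeCounts(x, normalization)
    share <- relativeAbundance(nmx, design)
    presence <- vapply(gsamp, function(s)
        rowMeans(m[, s, drop = FALSE] > 0), numeric(nrow(m)))

    ## q < alpha in every pairwise comparison involving g
    qpass <- matrix(TRUE, nrow(m), length(lv),
                    dimnames = list(rownames(m), lv))
    for (k in seq_len(ncol(pairs))) {
        a <- pairs[1L, k]; b <- pairs[2L, k]
        ok <- pairStats$q[pairStats$groupA == a &
                          pairStats$groupB == b] < alpha
        qpass[, a] <- qpass[, a] & ok
        qpass[, b] <- qpass[, b] & ok
    }

    grp_list <- lapply(lv, function(g) data.frame(
        protein = rownames(m), group = g,
        presence_fraction = presence[, g],
        relative_abundance = share[rownames(m), g],
        significant = presence[, g] >= presenceMin &
            !is.na(share[rownames(m), g]) &
            share[rownames(m), g] > shareMin & qpass[, g],
        stringsAsFactors = FALSE))
    groupStats <- do.call(rbind, grp_list)
    rownames(pairStats) <- rownames(groupStats) <- NULL
    new("DiffResult", pairStats = pairStats, groupStats = groupStats,
        params = list(alpha = alpha, presenceMin = presenceMin,
                      shareMin = shareMin, bhFamily = bhFamily,
                      normalization = normalization))
}
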