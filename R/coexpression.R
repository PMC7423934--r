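## Weighted co-expression network analysis: Pearson correlation ->
## soft-thresholded adjacency -> topological overlap -> average-linkage
## dendrogram -> dynamic tree cut -> hub eigen-proteins -> module-trait
## correlation.

#' Protein-protein Pearson correlation matrix
#'
#' @param nm a [NormalizedMatrix-class] or numeric matrix, proteins x
#'   samples, >= 3 samples; proteins with zero variance must be removed
#'   first (they have no defined correlation).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pearsonMatrix <- function(nm) {
    m <- if (is(nm, "NormalizedMatrix")) nm@.Data else as.matrix(nm)
    if (ncol(m) < 3) stop("need >= 3 samples for correlation")
    v <- apply(m, 1L, stats::var)
    if (any(v == 0))
        stop("zero-variance protein(s): ",
             paste(utils::head(rownames(m)[v == 0], 10), collapse = ", "))
    r <- stats::cor(t(m))
    diag(r) <- 1
    r
}

#' Soft-thresholded adjacency from correlation
#'
#' \code{signed}: ((1 + r)/2)^beta, the standard signed network in which
#' anticorrelated proteins are unconnected (default). \code{unsigned}:
#' |r|^beta. \code{dissimilarity}: ((1 - r)/2)^beta, the transform of the
#' signed dissimilarity; it connects anticorrelated pairs and is kept as a
#' fidelity option for reports that state the similarity that way round.
#' The diagonal is set to 1 by convention.
#'
#' @param corr correlation matrix.
#' @param power positive integer soft-threshold exponent beta.
#' @param mode one of \code{"signed"}, \code{"unsigned"},
#'   \code{"dissimilarity"}.
#' @return adjacency matrix in [0, 1].
#' @export
adjacencyFromCorrelation <- function(corr, power = 10,
                                     mode = c("signed", "unsigned",
                                              "dissimilarity")) {
    mode <- match.arg(mode)
    stopifnot(power >= 1)
    a <- switch(mode,
                signed = ((1 + corr) / 2)^power,
                unsigned = abs(corr)^power,
                dissimilarity = ((1 - corr) / 2)^power)
    a <- pmin(pmax(a, 0), 1)
    diag(a) <- 1
    a
}

#' Scale-free topology fit across candidate soft powers
#'
#' For each power beta, connectivities k_i = sum_{j != i} a_ij are binned
#' (default 10 equal-width bins of log10 k), and log10 of the empirical
#' degree frequency is regressed on log10 of the bin mean; the signed fit
#' index is -sign(slope) * R^2, so positive values indicate the decreasing
#' power-law shape. The recommended power is the smallest beta with signed
#' R^2 >= \code{rsqCut}, else the beta maximizing signed R^2.
#'
#' @param nm normalized matrix (or correlation matrix via \code{corr}).
#' @param powers integer vector of candidate betas (>= 2 values).
#' @param mode adjacency mode.
#' @param nBins histogram bins for the fit.
#' @param rsqCut signed R^2 threshold for the recommendation (default 0.8).
#' @param corr optional precomputed correlation matrix.
#' @return data.frame with columns \code{power}, \code{sft_rsq},
#'   \code{mean_k}; the recommended beta in attribute
#'   \code{"recommended"}.
#' @export
softThresholdFit <- function(nm, powers = c(1:10, 12, 14, 16, 18, 20),
                             mode = "signed", nBins = 10, rsqCut = 0.8,
                             corr = NULL) {
    if (length(powers) < 2) stop("need >= 2 candidate powers")
    if (is.null(corr)) corr <- pearsonMatrix(nm)
    res <- data.frame(power = powers, sft_rsq = NA_real_,
                      mean_k = NA_real_)
    for (i in seq_along(powers)) {
        a <- adjacencyFromCorrelation(corr, powers[i], mode)
        k <- colSums(a) - 1  # exclude self
        res$mean_k[i] <- mean(k)
        res$sft_rsq[i] <- .scale_free_rsq(k, nBins)
    }
    ok <- which(!is.na(res$sft_rsq) & res$sft_rsq >= rsqCut)
    rec <- if (length(ok)) res$power[ok[1]]
           else if (all(is.na(res$sft_rsq))) NA_integer_
           else res$power[which.max(res$sft_rsq)]
    attr(res, "recommended") <- rec
    res
}

## signed scale-free fit index of a connectivity vector
.scale_free_rsq <- function(k, nBins = 10) {
    k <- k[k > 0]
    if (length(unique(k)) < 2) return(NA_real_)
    br <- seq(min(log10(k)), max(log10(k)), length.out = nBins + 1L)
    br[1] <- br[1] - 1e-9
    bin <- cut(log10(k), br, include.lowest = TRUE)
    cnt <- tabulate(bin, nbins = nBins)
    kmean <- tapply(k, bin, mean)
    keep <- cnt > 0
    if (sum(keep) < 3) return(NA_real_)
    xx <- log10(kmean[keep])
    yy <- log10(cnt[keep] / sum(cnt))
    fit <- stats::lm(yy ~ xx)
    r2 <- summary(fit)$r.squared
    -sign(stats::coef(fit)[2]) * r2
}

#' Topological overlap matrix
#'
#' TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij) for i != j, where
#' l_ij = sum_{u != i,j} a_iu a_uj and k excludes the self term; TOM_ii = 1
#' by convention; a zero denominator yields 0.
#'
#' @param a symmetric adjacency matrix in [0, 1].
#' @return TOM similarity matrix in [0, 1].
#' @export
tomSimilarity <- function(a) {
    a <- as.matrix(a)
    if (!isSymmetric(unname(a), tol = 1e-8)) stop("adjacency not symmetric")
    if (any(a < 0 | a > 1)) stop("adjacency entries must lie in [0, 1]")
    diag(a) <- 0                      # work off-diagonal
    L <- a %*% a                      # sum_u a_iu a_uj (u != i,j since diag 0)
    k <- colSums(a)
    denom <- outer(k, k, pmin) + 1 - a
    tom <- (L + a) / denom
    tom[denom == 0] <- 0
    tom[!is.finite(tom)] <- 0
    tom <- pmin(pmax(tom, 0), 1)
    diag(tom) <- 1
    dimnames(tom) <- dimnames(a)
    tom
}

#' Average-linkage clustering of a TOM dissimilarity
#'
#' @param diss square symmetric dissimilarity with zero diagonal,
#'   typically \code{1 - tomSimilarity(a)}.
#' @return an \code{hclust} tree (UPGMA); \code{stats::hclust} breaks
#'   distance ties deterministically by the smaller cluster index.
#' @export
hclustAverage <- function(diss) {
    diss <- as.matrix(diss)
    if (any(is.na(diss)) || any(!is.finite(diss)))
        stop("dissimilarity contains NA/NaN")
    if (!isSymmetric(unname(diss), tol = 1e-8))
        stop("dissimilarity not symmetric")
    stats::hclust(stats::as.dist(diss), method = "average")
}

#' Hub eigen-protein of each module
#'
#' The eigen-protein of module m is its most intramodularly connected
#' member: argmax of kIM_i = sum_{j in m, j != i} a_ij, ties broken by
#' lexicographically smallest protein id.
#'
#' @param a adjacency matrix.
#' @param labels named integer module labels (0 = unassigned).
#' @return named character vector, module id -> protein id.
#' @export
eigenProteinOf <- function(a, labels) {
    mods <- sort(unique(labels[labels > 0]))
    out <- character(length(mods))
    names(out) <- as.character(mods)
    for (i in seq_along(mods)) {
        mem <- names(labels)[labels == mods[i]]
        sub <- a[mem, mem, drop = FALSE]
        kim <- colSums(sub) - diag(sub)
        best <- names(kim)[kim == max(kim)]
        out[i] <- sort(best)[1]
    }
    out
}

#' Module summary profiles
#'
#' Per-module expression profile over samples: either the hub
#' eigen-protein's own profile (default, \code{method = "hub"}) or the
#' first principal component of the module's standardized expression
#' (\code{method = "pca"}, the classical module eigengene, sign-anchored
#' to correlate positively with the module mean).
#'
#' @param nm normalized matrix.
#' @param labels module labels.
#' @param a adjacency (required for \code{"hub"}).
#' @param method \code{"hub"} or \code{"pca"}.
#' @return matrix, modules x samples.
#' @export
moduleSummary <- function(nm, labels, a = NULL,
                          method = c("hub", "pca")) {
    method <- match.arg(method)
    m <- if (is(nm, "NormalizedMatrix")) nm@.Data else as.matrix(nm)
    mods <- sort(unique(labels[labels > 0]))
    out <- matrix(NA_real_, length(mods), ncol(m),
                  dimnames = list(as.character(mods), colnames(m)))
    if (method == "hub") {
        if (is.null(a)) stop("adjacency required for hub summaries")
        ep <- eigenProteinOf(a, labels)
        for (md in names(ep)) out[md, ] <- m[ep[[md]], ]
    } else {
        for (i in seq_along(mods)) {
            mem <- names(labels)[labels == mods[i]]
            sub <- t(scale(t(m[mem, , drop = FALSE])))
            sub[!is.finite(sub)] <- 0
            pc <- stats::prcomp(t(sub), center = FALSE, scale. = FALSE)
            v <- pc$x[, 1]
            if (stats::cor(v, colMeans(sub)) < 0) v <- -v
            out[i, ] <- v
        }
    }
    out
}

#' Module-trait correlation
#'
#' Pearson correlation between each module's eigen-protein profile and
#' each one-vs-rest binary trait vector, with p from the t transform
#' t = r sqrt((n - 2)/(1 - r^2)) on n - 2 df (two-sided) and BH adjustment
#' per trait across modules (\code{bhFamily = "pooled"} adjusts all
#' module x trait p-values as one family). Modules with a constant profile
#' get NA statistics.
#'
#' @param nm normalized matrix (samples must match the design).
#' @param eigen named character module -> protein (from
#'   [eigenProteinOf()]), or a modules x samples profile matrix.
#' @param design a [GroupDesign-class].
#' @param bhFamily \code{"per_trait"} (default) or \code{"pooled"}.
#' @param rCut flag threshold on |r| (default 0.5).
#' @param alpha flag threshold on q (default 0.05).
#' @return data.frame: module, trait, r, p, q, high_cor (|r| > rCut),
#'   significant (q < alpha).
#' @export
moduleTraitCorrelation <- function(nm, eigen, design,
                                   bhFamily = c("per_trait", "pooled"),
                                   rCut = 0.5, alpha = 0.05) {
    bhFamily <- match.arg(bhFamily)
    m <- if (is(nm, "NormalizedMatrix")) nm@.Data else as.matrix(nm)
    tv <- traitVectors(design)
    if (is.matrix(eigen)) {
        prof <- eigen[, rownames(tv), drop = FALSE]
    } else {
        prof <- m[unname(eigen), rownames(tv), drop = FALSE]
        rownames(prof) <- names(eigen)
    }
    n <- ncol(prof)
    if (n < 3) stop("need >= 3 samples")
    res <- expand.grid(module = rownames(prof), trait = colnames(tv),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    res$r <- NA_real_; res$p <- NA_real_
    for (i in seq_len(nrow(res))) {
        x <- prof[res$module[i], ]
        y <- tv[, res$trait[i]]
        if (stats::sd(x) == 0 || stats::sd(y) == 0) next
        r <- stats::cor(x, y)
        res$r[i] <- r
        if (abs(r) >= 1) { res$p[i] <- 0; next }
        tt <- r * sqrt((n - 2) / (1 - r^2))
        res$p[i] <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
    }
    res$q <- NA_real_
    ok <- !is.na(res$p)
    if (any(ok)) {
        if (bhFamily == "pooled") res$q[ok] <- bhAdjust(res$p[ok])
        else res$q[ok] <- stats::ave(res$p[ok], res$trait[ok],
                                     FUN = bhAdjust)
    }
    res$high_cor <- !is.na(res$r) & abs(res$r) > rCut
    res$significant <- !is.na(res$q) & res$q < alpha
    res
}

#' Run the full co-expression pipeline
#'
#' Correlation, soft-thresholded adjacency, TOM, average-linkage
#' dendrogram of 1 - TOM, dynamic tree cut, hub eigen-proteins and
#' module-trait statistics, collected in a [CoexprModel-class].
#'
#' @param nm a [NormalizedMatrix-class] (proteins x samples).
#' @param design a [GroupDesign-class] (optional; omit to skip trait
#'   statistics).
#' @param power soft threshold beta (default 10).
#' @param mode adjacency mode (default "signed").
#' @param minModuleSize minimum module size (default 10).
#' @param deepSplit split sensitivity 0-4 (default 4).
#' @param bhFamily BH family for trait statistics.
#' @return a [CoexprModel-class].
#' @examples
#' sim <- simulateCounts(simSpec(nProteins = 60, seed = 7,
#'     modules = list(list(size = 20, group = "LPA", loading = 0.9))))
#' nm <- normalizeCounts(aggregateReplicates(sim$counts), "log2_total")
#' fit <- buildCoexprModel(nm, sim$design, minModuleSize = 5)
#' fit
#' @export
buildCoexprModel <- function(nm, design = NULL, power = 10,
                             mode = "signed", minModuleSize = 10,
                             deepSplit = 4, bhFamily = "per_trait") {
    ## proteins with a flat profile have no defined correlation: drop them
    v <- apply(if (is(nm, "NormalizedMatrix")) nm@.Data else nm, 1L,
               stats::var)
    if (any(v == 0)) {
        message("dropping ", sum(v == 0),
                " zero-variance protein(s) before correlation")
        nm <- new("NormalizedMatrix",
                  (if (is(nm, "NormalizedMatrix")) nm@.Data else nm)[
                      v > 0, , drop = FALSE],
                  method = if (is(nm, "NormalizedMatrix")) nm@method
                           else "none")
    }
    corr <- pearsonMatrix(nm)
    a <- adjacencyFromCorrelation(corr, power, mode)
    tom <- tomSimilarity(a)
    diss <- 1 - tom
    diag(diss) <- 0
    hc <- hclustAverage(diss)
    labels <- cutreeDynamicHybrid(hc, deepSplit = deepSplit,
                                  minModuleSize = minModuleSize)
    ep <- eigenProteinOf(a, labels)
    ts <- if (!is.null(design) && length(ep))
        moduleTraitCorrelation(nm, ep, design, bhFamily = bhFamily)
    else data.frame()
    new("CoexprModel", corr = corr, power = power, mode = mode,
        adjacency = a, tom = tom, dendrogram = hc, labels = labels,
        eigenProteins = ep, traitStats = ts)
}
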