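## Oncoprint-style summaries of somatic mutations and copy-number states,
## and the copy-number-loss burden comparison between two subtype groups.

#' Summarize mutations and copy-number states per sample
#'
#' Copy-number loss is strict CN < \code{lossThreshold} (so diploid CN = 2
#' is not a loss under the default 2), gain is CN > \code{gainThreshold};
#' a gene with both a mutation record and a CNV takes a combined state.
#'
#' @param cn gene x sample copy-number matrix (from
#'   [readCopyNumberMatrix()]).
#' @param mutations mutation data.frame (from [readMutationTable()]); its
#'   samples must appear in \code{cn}.
#' @param lossThreshold CN below which a gene counts as lost (default 2).
#' @param gainThreshold CN above which a gene counts as gained (default
#'   2.5; must exceed \code{lossThreshold}).
#' @return list with \code{perSample} (data.frame: sample, n_mutations,
#'   n_cn_gain, n_cn_loss) and \code{states} (gene x sample character
#'   matrix over \{none, mutation, gain, loss, mutation+gain,
#'   mutation+loss\}).
#' @export
summarizeAlterations <- function(cn, mutations = NULL, lossThreshold = 2,
                                 gainThreshold = 2.5) {
    stopifnot(lossThreshold > 0, gainThreshold > lossThreshold)
    if (is.null(mutations)) mutations <- readMutationTable(NULL)
    extra <- setdiff(unique(mutations$sample_id), colnames(cn))
    if (length(extra))
        stop("mutation sample(s) absent from copy-number matrix: ",
             paste(extra, collapse = ", "))
    states <- matrix("none", nrow(cn), ncol(cn), dimnames = dimnames(cn))
    states[cn < lossThreshold] <- "loss"
    states[cn > gainThreshold] <- "gain"
    if (nrow(mutations)) {
        for (i in seq_len(nrow(mutations))) {
            gn <- mutations$gene[i]; sm <- mutations$sample_id[i]
            if (!gn %in% rownames(cn)) next
            states[gn, sm] <- switch(states[gn, sm],
                                     none = "mutation",
                                     loss = "mutation+loss",
                                     gain = "mutation+gain",
                                     states[gn, sm])
        }
    }
    perSample <- data.frame(
        sample = colnames(cn),
        n_mutations = vapply(colnames(cn), function(s)
            sum(mutations$sample_id == s), integer(1)),
        n_cn_gain = colSums(cn > gainThreshold),
        n_cn_loss = colSums(cn < lossThreshold),
        stringsAsFactors = FALSE)
    rownames(perSample) <- NULL
    list(perSample = perSample, states = states,
         thresholds = c(loss = lossThreshold, gain = gainThreshold))
}

#' Compare copy-number-loss burden between two groups
#'
#' Two-sided test on the per-sample number of genes with copy-number loss.
#' The default Mann-Whitney test uses an exact p-value by full enumeration
#' of all choose(nA + nB, nA) group assignments whenever both groups have
#' at most \code{exactMax} samples (the enumeration handles ties, which
#' the normal approximation and \code{stats::wilcox.test}'s exact path do
#' not); larger groups fall back to \code{stats::wilcox.test}. A t-test is
#' available behind \code{test = "ttest"}. All-identical burdens give
#' p = 1 with a warning.
#'
#' @param summary result of [summarizeAlterations()], or a named numeric
#'   vector of per-sample burdens.
#' @param design a [GroupDesign-class].
#' @param groupA,groupB the two groups to compare (>= 2 samples each).
#' @param test \code{"mannwhitney"} (default) or \code{"ttest"}.
#' @param exactMax largest per-group size for exact enumeration (default
#'   6).
#' @return list with \code{statistic}, \code{p.value}, \code{method},
#'   \code{burdenA}, \code{burdenB}.
#' @export
compareBurden <- function(summary, design, groupA, groupB,
                          test = c("mannwhitney", "ttest"), exactMax = 6) {
    test <- match.arg(test)
    burden <- if (is.list(summary) && !is.null(summary$perSample))
        structure(summary$perSample$n_cn_loss, names = summary$perSample$sample)
    else summary
    asg <- groupAssignments(design)
    for (g in c(groupA, groupB))
        if (!g %in% groupLevels(design)) stop("unknown group: ", g)
    sA <- names(asg)[asg == groupA]; sB <- names(asg)[asg == groupB]
    if (length(sA) < 2 || length(sB) < 2)
        stop("both groups need >= 2 samples")
    miss <- setdiff(c(sA, sB), names(burden))
    if (length(miss)) stop("no burden value for sample(s): ",
                           paste(miss, collapse = ", "))
    a <- unname(burden[sA]); b <- unname(burden[sB])
    if (length(unique(c(a, b))) == 1L) {
        warning("all burdens identical; p = 1")
        return(list(statistic = NA_real_, p.value = 1,
                    method = "degenerate", burdenA = a, burdenB = b))
    }
    if (test == "ttest") {
        ht <- stats::t.test(a, b)
        return(list(statistic = unname(ht$statistic), p.value = ht$p.value,
                    method = "Welch t-test", burdenA = a, burdenB = b))
    }
    if (length(a) <= exactMax && length(b) <= exactMax) {
        res <- .mw_exact(a, b)
        return(list(statistic = res$U, p.value = res$p,
                    method = "Mann-Whitney (exact enumeration)",
                    burdenA = a, burdenB = b))
    }
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                              correct = TRUE))
    list(statistic = unname(ht$statistic), p.value = ht$p.value,
         method = "Mann-Whitney (normal approximation)",
         burdenA = a, burdenB = b)
}

## exact two-sided Mann-Whitney p by full enumeration of label
## assignments; ties handled through midranks. Two-sided p doubles the
## smaller tail probability of the rank-sum (capped at 1).
.mw_exact <- function(a, b) {
    z <- c(a, b)
    nA <- length(a); n <- length(z)
    rk <- rank(z)
    obs <- sum(rk[seq_len(nA)])
    idx <- utils::combn(n, nA)
    sums <- colSums(matrix(rk[idx], nrow = nA))
    lo <- mean(sums <= obs); hi <- mean(sums >= obs)
    U <- obs - nA * (nA + 1) / 2
    list(U = U, p = min(1, 2 * min(lo, hi)))
}
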