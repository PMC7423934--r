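## Replicate aggregation, normalization and the characteristic-protein
## presence filter applied before differential and network analysis.

#' Aggregate replicate runs into one column per sample
#'
#' Spectral counts of technical replicates (e.g. triplicate LC-MS/MS runs)
#' are combined per sample. \code{sum} preserves integrality and total
#' counts and is the default because the downstream G-test operates on raw
#' counts; \code{mean_round} divides by the replicate number and rounds
#' half-up.
#'
#' @param x a [SpectralCountSet-class] (with or without replicates).
#' @param method \code{"sum"} or \code{"mean_round"}.
#' @return a [SpectralCountSet-class] with one column per sample, sample
#'   order preserved.
#' @export
aggregateReplicates <- function(x, method = c("sum", "mean_round")) {
    method <- match.arg(method)
    stopifnot(is(x, "SpectralCountSet"))
    m <- counts(x)
    samp <- SummarizedExperiment::colData(x)$sample
    sids <- sampleIds(x)
    out <- matrix(0, nrow(m), length(sids),
                  dimnames = list(rownames(m), sids))
    for (s in sids) {
        block <- m[, samp == s, drop = FALSE]
        out[, s] <- if (method == "sum") rowSums(block)
                    else floor(rowMeans(block) + 0.5)  # round half-up
    }
    SpectralCountSet(out)
}

#' Normalize aggregated spectral counts
#'
#' \code{total_count} scales each sample column to sum to 1 (compositional
#' share); \code{log2_total} is \code{log2(1 + 1e4 * share)}, a
#' depth-stabilized log scale suited to correlation analysis; \code{none}
#' passes the raw counts through.
#'
#' @param x a [SpectralCountSet-class], one column per sample.
#' @param method normalization tag.
#' @return a [NormalizedMatrix-class].
#' @export
normalizeCounts <- function(x,
                            method = c("log2_total", "total_count", "none")) {
    method <- match.arg(method)
    m <- if (is(x, "SpectralCountSet")) counts(x) else as.matrix(x)
    if (method == "none")
        return(new("NormalizedMatrix", m, method = "none"))
    tot <- colSums(m)
    if (any(tot == 0))
        stop("all-zero sample column(s): ",
             paste(colnames(m)[tot == 0], collapse = ", "))
    share <- sweep(m, 2L, tot, "/")
    out <- if (method == "total_count") share else log2(1 + 1e4 * share)
    new("NormalizedMatrix", out, method = method)
}

#' Characteristic proteins of each subtype
#'
#' A protein is characteristic of a group when it is observed (SpC > 0) in
#' at least \code{minSamples} samples of that group; the default 4
#' implements "in more than three samples". The \code{rule = "nonneg"}
#' variant admits SpC >= 0, i.e. every protein in every group of size >=
#' \code{minSamples}; it is retained for fidelity to reports that state the
#' threshold that way, but presence is the meaningful filter.
#'
#' @param x aggregated [SpectralCountSet-class].
#' @param design a [GroupDesign-class].
#' @param minSamples minimum number of group samples the protein must be
#'   seen in.
#' @param rule \code{"presence"} (SpC > 0) or \code{"nonneg"} (SpC >= 0).
#' @return named list, one character vector of protein ids per group.
#' @export
characteristicProteins <- function(x, design, minSamples = 4,
                                   rule = c("presence", "nonneg")) {
    rule <- match.arg(rule)
    stopifnot(minSamples >= 1)
    m <- counts(x)
    .check_design(m, design)
    asg <- groupAssignments(design)
    out <- list()
    for (g in groupLevels(design)) {
        gs <- names(asg)[asg == g]
        if (length(gs) < minSamples) {
            warning("group ", g, " has fewer than ", minSamples,
                    " samples; characteristic set empty")
            out[[g]] <- character()
            next
        }
        obs <- if (rule == "presence") m[, gs, drop = FALSE] > 0
               else m[, gs, drop = FALSE] >= 0
        out[[g]] <- rownames(m)[rowSums(obs) >= minSamples]
    }
    out
}

#' Overlap counts among per-group protein sets
#'
#' Venn-style summary: for each combination of groups, the number of
#' proteins characteristic of exactly that combination.
#'
#' @param sets named list of character vectors, as returned by
#'   [characteristicProteins()].
#' @return data.frame with columns \code{groups} (combination label, groups
#'   joined by \code{&}) and \code{n}.
#' @export
overlapCounts <- function(sets) {
    all_p <- unique(unlist(sets))
    member <- vapply(sets, function(s) all_p %in% s, logical(length(all_p)))
    if (length(all_p) == 1L) member <- matrix(member, nrow = 1L,
                                              dimnames = list(NULL, names(sets)))
    key <- apply(member, 1L, function(r)
        paste(names(sets)[r], collapse = "&"))
    tab <- table(key)
    data.frame(groups = names(tab), n = as.integer(tab),
               stringsAsFactors = FALSE)
}

## shared guard: matrix samples must match design samples
.check_design <- function(m, design) {
    if (!setequal(colnames(m), samples(design)))
        stop("samples in matrix and design differ")
    invisible(TRUE)
}
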