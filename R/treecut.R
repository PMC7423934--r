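## Dynamic hybrid tree cut: adaptive decomposition of a dendrogram into
## modules, processed in merge order. Branches grow by absorbing
## singletons and small side-branches (which handles the chained,
## one-leaf-at-a-time accretion typical of average-linkage trees); when
## two branch-like clusters meet, each one that satisfies the
## deepSplit-dependent tightness and gap criteria is finalized as a
## module. Leaves never covered by a finalized branch stay unassigned
## (label 0). Labels are renumbered by decreasing module size.

## deepSplit in 0..4 maps to the maximum core scatter on the normalized
## height scale; the minimum gap is (1 - maxCoreScatter) * 3/4. Higher
## deepSplit tolerates looser branches and smaller gaps, i.e. splits more
## aggressively. Both thresholds are rescaled to the tree at hand between
## the 5th percentile of merge heights and the tree top, so they adapt to
## where the dissimilarities actually live.
.deep_split_params <- function(deepSplit, hn) {
    if (!deepSplit %in% 0:4) stop("deepSplit must be in 0..4")
    mcs <- c(0.64, 0.73, 0.82, 0.91, 0.95)[deepSplit + 1L]
    gap <- (1 - mcs) * 3 / 4
    q5 <- stats::quantile(hn, 0.05, names = FALSE)
    list(maxCoreScatter = q5 + mcs * (1 - q5), minGap = gap * (1 - q5))
}

#' Dynamic hybrid cut of a dendrogram into modules
#'
#' Decomposes an average-linkage tree of TOM dissimilarities into modules
#' of at least \code{minModuleSize} proteins. Merges are processed bottom
#' up: a growing branch absorbs singletons and sub-threshold
#' side-branches; when two clusters of at least \code{minModuleSize}
#' leaves meet (or a qualifying branch joins already-finalized
#' structure), each branch whose core scatter (mean internal merge
#' height) stays below the deepSplit-dependent ceiling (0.64, 0.73,
#' 0.82, 0.91, 0.95 of the calibrated height range for deepSplit 0-4) and
#' whose gap to the merge height is at least (1 - ceiling) * 3/4 is
#' finalized as a module. Heights are normalized to the tree top and both
#' thresholds are calibrated between the 5th percentile of merge heights
#' and 1, so the criteria adapt to the scale on which the dissimilarities
#' live. Leaves in no finalized branch get label 0.
#'
#' @param hc an \code{hclust} tree with leaf labels.
#' @param deepSplit integer 0-4, split sensitivity (default 4, the most
#'   sensitive).
#' @param minModuleSize minimum leaves per module (default 10, >= 2).
#' @return named integer vector of module labels over the leaves, 0 for
#'   unassigned, modules numbered 1, 2, ... by decreasing size.
#' @export
cutreeDynamicHybrid <- function(hc, deepSplit = 4, minModuleSize = 10) {
    stopifnot(inherits(hc, "hclust"), minModuleSize >= 2)
    if (is.null(hc$labels)) stop("dendrogram has no leaf labels")
    n <- length(hc$labels)
    labels_out <- structure(integer(n), names = hc$labels)
    if (n < minModuleSize) {
        .deep_split_params(deepSplit, 0)  # still validate deepSplit
        return(labels_out)
    }
    nm <- nrow(hc$merge)
    hmax <- max(hc$height)
    hn <- if (hmax > 0) hc$height / hmax else rep(0, nm)
    par <- .deep_split_params(deepSplit, hn)

    ## branch state per internal node: live branches carry their leaves
    ## and the running mean of internal merge heights (the core scatter)
    live <- function(leaves, hsum, hcnt)
        list(dead = FALSE, leaves = leaves, hsum = hsum, hcnt = hcnt)
    DEAD <- list(dead = TRUE)
    state <- vector("list", nm)
    finals <- list()

    scat <- function(b) b$hsum / b$hcnt
    branchlike <- function(b) length(b$leaves) >= minModuleSize
    qual <- function(b, h)
        branchlike(b) && scat(b) <= par$maxCoreScatter &&
            (h - scat(b)) >= par$minGap
    finalize <- function(b) finals[[length(finals) + 1L]] <<- b$leaves

    for (i in seq_len(nm)) {
        h <- hn[i]
        ch <- hc$merge[i, ]
        side <- lapply(ch, function(c)
            if (c < 0) live(-c, 0, 0L) else state[[c]])
        d1 <- side[[1]]$dead; d2 <- side[[2]]$dead
        if (d1 && d2) { state[[i]] <- DEAD; next }
        if (d1 || d2) {
            ## live side meets finalized structure: close it if it
            ## qualifies, otherwise it keeps growing past the dead part
            b <- if (d1) side[[2]] else side[[1]]
            if (qual(b, h)) { finalize(b); state[[i]] <- DEAD }
            else state[[i]] <- live(b$leaves, b$hsum + h, b$hcnt + 1L)
            next
        }
        b1 <- side[[1]]; b2 <- side[[2]]
        if (branchlike(b1) && branchlike(b2)) {
            q1 <- qual(b1, h); q2 <- qual(b2, h)
            if (q1) finalize(b1)
            if (q2) finalize(b2)
            state[[i]] <- if (q1 && q2) DEAD
                else if (q1) live(b2$leaves, b2$hsum + h, b2$hcnt + 1L)
                else if (q2) live(b1$leaves, b1$hsum + h, b1$hcnt + 1L)
                else live(c(b1$leaves, b2$leaves),
                          b1$hsum + b2$hsum + h, b1$hcnt + b2$hcnt + 1L)
        } else {
            ## absorb singletons / sub-threshold side-branches
            state[[i]] <- live(c(b1$leaves, b2$leaves),
                               b1$hsum + b2$hsum + h,
                               b1$hcnt + b2$hcnt + 1L)
        }
    }
    root <- state[[nm]]
    if (!root$dead && branchlike(root) &&
        scat(root) <= par$maxCoreScatter)
        finalize(root)

    if (!length(finals)) return(labels_out)
    ord <- order(lengths(finals), decreasing = TRUE)
    for (k in seq_along(ord))
        labels_out[finals[[ord[k]]]] <- k
    labels_out
}
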