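## Cohort descriptive statistics: per-group mean +/- SD and one-way ANOVA
## across subtype groups, as printed in clinical summary tables.

#' Per-group descriptive statistics
#'
#' Means and standard deviations of one clinical variable per group. The
#' default SD uses divisor n (population form), which is how the cohort
#' table's printed values recompute from the per-patient entries; the
#' sample form (divisor n - 1) sits behind \code{sd = "sample"}. Values
#' are returned at full precision; round only at presentation.
#'
#' @param values named numeric vector, one value per sample.
#' @param design a [GroupDesign-class]; every sample must have a value.
#' @param sd \code{"population"} (default) or \code{"sample"}.
#' @return data.frame: group, n, mean, sd.
#' @examples
#' coh <- luadCohort()
#' d <- GroupDesign(coh$sample_id, coh$group)
#' describeGroups(setNames(coh$age, coh$sample_id), d)
#' @export
describeGroups <- function(values, design,
                           sd = c("population", "sample")) {
    sd <- match.arg(sd)
    miss <- setdiff(samples(design), names(values))
    if (length(miss)) stop("missing value for sample(s): ",
                           paste(miss, collapse = ", "))
    v <- values[samples(design)]
    if (any(is.na(v))) stop("NA value(s) in input")
    asg <- groupAssignments(design)
    out <- do.call(rbind, lapply(groupLevels(design), function(g) {
        x <- unname(v[names(asg)[asg == g]])
        s <- if (sd == "population") sqrt(mean((x - mean(x))^2))
             else stats::sd(x)
        data.frame(group = g, n = length(x), mean = mean(x), sd = s,
                   stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}

#' One-way fixed-effects ANOVA across groups
#'
#' Classical equal-variance one-way ANOVA of a clinical variable against
#' the subtype grouping (delegating to \code{stats::oneway.test} with
#' \code{var.equal = TRUE}). Zero within-group variance with unequal
#' means is the F = Inf boundary and returns p = 0 explicitly.
#'
#' @param values named numeric vector, one value per sample.
#' @param design a [GroupDesign-class] with >= 2 groups and total n above
#'   the group count.
#' @return list with \code{F} and \code{p}.
#' @export
oneWayAnova <- function(values, design) {
    miss <- setdiff(samples(design), names(values))
    if (length(miss)) stop("missing value for sample(s): ",
                           paste(miss, collapse = ", "))
    v <- values[samples(design)]
    g <- groupAssignments(design)
    if (nlevels(g) < 2) stop("ANOVA needs >= 2 groups")
    if (length(v) <= nlevels(g)) stop("total n must exceed group count")
    ssw <- sum(unlist(lapply(levels(g), function(l) {
        x <- v[g == l]; sum((x - mean(x))^2)
    })))
    if (ssw == 0) {
        means <- tapply(v, g, mean)
        if (max(means) > min(means)) return(list(F = Inf, p = 0))
        return(list(F = 0, p = 1))
    }
    ht <- stats::oneway.test(v ~ g, var.equal = TRUE)
    list(F = unname(ht$statistic), p = unname(ht$p.value))
}
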