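#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Spectral-count container
#'
#' An S4 container for protein x run spectral-count matrices, extending
#' \linkS4class{SummarizedExperiment}. Rows are proteins, columns are runs;
#' when a sample was acquired in replicate (e.g. triplicate LC-MS/MS runs)
#' several columns map to the same biological sample via the \code{sample}
#' column of \code{colData}.
#'
#' Validity requires: a single \code{"counts"} assay of non-negative
#' integral values; unique, non-empty protein (row) names; unique column
#' names; a \code{sample} column in \code{colData}.
#'
#' @slot . inherits all slots from \code{SummarizedExperiment}.
#' @seealso [SpectralCountSet()] for construction,
#'   [readCountMatrix()] to read one from TSV,
#'   [aggregateReplicates()] to collapse replicate runs.
#' @exportClass SpectralCountSet
setClass("SpectralCountSet", contains = "SummarizedExperiment")

.validSpectralCountSet <- function(object) {
    msg <- NULL
    if (!("counts" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'counts' is required")
    else {
        m <- SummarizedExperiment::assay(object, "counts")
        if (any(is.na(m)))
            msg <- c(msg, "counts contain NA")
        else {
            if (any(m < 0))
                msg <- c(msg, "counts must be non-negative")
            if (any(m != round(m)))
                msg <- c(msg, "counts must be integral")
        }
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "protein (row) names must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "column names must be present and unique")
    if (!("sample" %in% colnames(SummarizedExperiment::colData(object))))
        msg <- c(msg, "colData must have a 'sample' column")
    if (is.null(msg)) TRUE else msg
}
setValidity("SpectralCountSet", .validSpectralCountSet)

#' Construct a SpectralCountSet
#'
#' @param counts numeric matrix of non-negative integral spectral counts,
#'   proteins in rows (rownames mandatory), runs in columns.
#' @param sample character vector mapping each column to its biological
#'   sample; defaults to the column names (one run per sample).
#' @param replicate optional character vector of run labels within sample.
#' @return a [SpectralCountSet-class] object.
#' @examples
#' m <- matrix(c(3L, 0L, 5L, 2L, 1L, 4L), nrow = 3,
#'             dimnames = list(c("P1", "P2", "P3"), c("S1", "S2")))
#' SpectralCountSet(m)
#' @export
SpectralCountSet <- function(counts, sample = colnames(counts),
                             replicate = NULL) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "double"
    cd <- DataFrame(sample = as.character(sample), row.names = colnames(counts))
    if (!is.null(replicate))
        cd$replicate <- as.character(replicate)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = cd)
    new("SpectralCountSet", se)
}

#' @describeIn SpectralCountSet-class spectral-count assay matrix.
#' @param object,x a \code{SpectralCountSet}.
#' @export
setMethod("counts", "SpectralCountSet", function(object)
    SummarizedExperiment::assay(object, "counts"))

#' @describeIn SpectralCountSet-class unique biological sample identifiers,
#'   in first-appearance order.
#' @export
setMethod("sampleIds", "SpectralCountSet", function(x)
    unique(SummarizedExperiment::colData(x)$sample))

#' @describeIn SpectralCountSet-class TRUE when any sample has more than one
#'   run column.
#' @export
setMethod("hasReplicates", "SpectralCountSet", function(x)
    anyDuplicated(SummarizedExperiment::colData(x)$sample) > 0)

#' @describeIn SpectralCountSet-class named integer vector of run counts per
#'   sample.
#' @export
setMethod("replicatesPerSample", "SpectralCountSet", function(x) {
    s <- SummarizedExperiment::colData(x)$sample
    tab <- table(factor(s, levels = unique(s)))
    structure(as.integer(tab), names = names(tab))
})

setMethod("show", "SpectralCountSet", function(object) {
    cat("SpectralCountSet:", nrow(object), "proteins x",
        ncol(object), "runs (", length(sampleIds(object)), "samples )\n")
    callNextMethod()
})

#' Group design for a subtype cohort
#'
#' Maps each biological sample to exactly one subtype group (e.g. AIS, MIA,
#' LPA) and derives one-vs-rest binary trait vectors used as clinical traits
#' in module-trait correlation.
#'
#' @slot samples character, unique sample identifiers.
#' @slot groups factor of the same length, the group of each sample.
#' @seealso [GroupDesign()], [traitVectors()], [readSampleMetadata()].
#' @exportClass GroupDesign
setClass("GroupDesign",
         representation(samples = "character", groups = "factor"))

setValidity("GroupDesign", function(object) {
    msg <- NULL
    if (length(object@samples) != length(object@groups))
        msg <- c(msg, "samples and groups must have equal length")
    if (anyDuplicated(object@samples))
        msg <- c(msg, "duplicate sample ids")
    if (any(is.na(object@groups)))
        msg <- c(msg, "every sample needs a group")
    if (is.null(msg)) TRUE else msg
})

#' Construct a GroupDesign
#'
#' @param samples character vector of sample identifiers.
#' @param groups character or factor of group labels, parallel to
#'   \code{samples}. Groups with fewer than 2 samples are allowed at load
#'   time (a warning is emitted) but pairwise analyses refuse them.
#' @return a [GroupDesign-class].
#' @examples
#' GroupDesign(paste0("S", 1:4), c("A", "A", "B", "B"))
#' @export
GroupDesign <- function(samples, groups) {
    groups <- if (is.factor(groups)) droplevels(groups)
              else factor(groups, levels = unique(as.character(groups)))
    d <- new("GroupDesign", samples = as.character(samples), groups = groups)
    sz <- groupSizes(d)
    if (any(sz < 2))
        warning("group(s) with < 2 samples, unusable for pairwise analysis: ",
                paste(names(sz)[sz < 2], collapse = ", "))
    d
}

#' @describeIn GroupDesign-class sample identifiers.
#' @param x,object a \code{GroupDesign}.
#' @export
setMethod("samples", "GroupDesign", function(x) x@samples)

#' @describeIn GroupDesign-class group label of each sample, as a named
#'   factor.
#' @export
setMethod("groupAssignments", "GroupDesign", function(x)
    structure(x@groups, names = x@samples))

#' @describeIn GroupDesign-class declared group labels.
#' @export
setMethod("groupLevels", "GroupDesign", function(x) levels(x@groups))

#' @describeIn GroupDesign-class named integer vector of group sizes.
#' @export
setMethod("groupSizes", "GroupDesign", function(x) {
    tab <- table(x@groups)
    structure(as.integer(tab), names = names(tab))
})

#' @describeIn GroupDesign-class samples-by-groups 0/1 matrix of one-vs-rest
#'   trait vectors; column sums equal group sizes.
#' @export
setMethod("traitVectors", "GroupDesign", function(x) {
    m <- vapply(groupLevels(x), function(g) as.integer(x@groups == g),
                integer(length(x@samples)))
    rownames(m) <- x@samples
    m
})

setMethod("show", "GroupDesign", function(object) {
    sz <- groupSizes(object)
    cat("GroupDesign:", length(object@samples), "samples in",
        length(sz), "groups (",
        paste(names(sz), sz, sep = "=", collapse = ", "), ")\n")
})

#' Normalized abundance matrix
#'
#' A protein x sample matrix of normalized spectral-count abundances,
#' tagged with the normalization used. \code{total_count} columns sum to 1;
#' \code{log2_total} is log2(1 + 1e4 * total-count share); \code{none}
#' passes raw counts through.
#'
#' @slot .Data numeric matrix.
#' @slot method normalization tag.
#' @seealso [normalizeCounts()].
#' @exportClass NormalizedMatrix
setClass("NormalizedMatrix", contains = "matrix",
         representation(method = "character"))

setValidity("NormalizedMatrix", function(object) {
    msg <- NULL
    if (any(!is.finite(object@.Data)))
        msg <- c(msg, "values must be finite")
    if (any(object@.Data < 0))
        msg <- c(msg, "values must be >= 0")
    if (length(object@method) != 1L ||
        !object@method %in% c("total_count", "log2_total", "none"))
        msg <- c(msg, "method must be one of total_count, log2_total, none")
    if (identical(object@method, "total_count")) {
        cs <- colSums(object@.Data)
        if (any(abs(cs[cs > 0] - 1) > 1e-9))
            msg <- c(msg, "total_count columns must sum to 1")
    }
    if (is.null(msg)) TRUE else msg
})

#' @describeIn NormalizedMatrix-class the normalization tag.
#' @param x a \code{NormalizedMatrix}.
#' @export
setMethod("normMethod", "NormalizedMatrix", function(x) x@method)

#' Weighted co-expression network model
#'
#' Holds every intermediate of the co-expression analysis: the Pearson
#' correlation matrix, the soft-thresholded adjacency, the topological
#' overlap matrix (TOM), the average-linkage dendrogram of 1 - TOM, module
#' labels from the dynamic tree cut (0 = unassigned), the hub eigen-protein
#' of each module, and module-trait correlation statistics.
#'
#' @slot corr protein x protein Pearson correlation matrix.
#' @slot power soft-threshold exponent beta.
#' @slot mode adjacency transform ("signed", "unsigned" or "dissimilarity").
#' @slot adjacency soft-thresholded adjacency, entries in [0, 1], unit
#'   diagonal.
#' @slot tom topological overlap matrix, unit diagonal.
#' @slot dendrogram \code{hclust} tree of 1 - TOM, average linkage.
#' @slot labels named integer module labels, renumbered by decreasing size.
#' @slot eigenProteins named character, module id -> hub protein.
#' @slot traitStats data.frame of per (module, trait) r, p, q and flags.
#' @seealso [buildCoexprModel()].
#' @exportClass CoexprModel
setClass("CoexprModel",
         representation(corr = "matrix", power = "numeric", mode = "character",
                        adjacency = "matrix", tom = "matrix",
                        dendrogram = "ANY", labels = "integer",
                        eigenProteins = "character",
                        traitStats = "data.frame"))

setMethod("show", "CoexprModel", function(object) {
    nmod <- length(unique(object@labels[object@labels > 0]))
    cat("CoexprModel:", nrow(object@corr), "proteins,",
        nmod, "modules (beta =", object@power,
        ", mode =", object@mode, ")\n")
    if (nmod > 0) {
        sz <- sort(table(object@labels[object@labels > 0]),
                   decreasing = TRUE)
        cat("  module sizes:", paste(utils::head(sz, 8), collapse = " "),
            if (nmod > 8) "...\n" else "\n")
    }
    cat("  unassigned:", sum(object@labels == 0), "\n")
})

#' @describeIn CoexprModel-class named integer module labels.
#' @param x a \code{CoexprModel}.
#' @export
setMethod("moduleLabels", "CoexprModel", function(x) x@labels)

#' @describeIn CoexprModel-class named character of hub eigen-proteins.
#' @export
setMethod("eigenProteins", "CoexprModel", function(x) x@eigenProteins)

#' @describeIn CoexprModel-class data.frame of module-trait statistics.
#' @export
setMethod("traitStats", "CoexprModel", function(x) x@traitStats)

#' Differential-expression result
#'
#' Result of the pairwise G-statistic analysis: one row per (protein, group
#' pair) with G, the Williams divisor, adjusted G, p and BH q; and one row
#' per (protein, group) with the presence fraction, relative abundance and
#' the three-part significance flag.
#'
#' @slot pairStats data.frame: protein, groupA, groupB, G, q_williams,
#'   G_adj, p, q.
#' @slot groupStats data.frame: protein, group, presence_fraction,
#'   relative_abundance, significant.
#' @slot params list of the thresholds used.
#' @seealso [significantProteins()].
#' @exportClass DiffResult
setClass("DiffResult",
         representation(pairStats = "data.frame", groupStats = "data.frame",
                        params = "list"))

setMethod("show", "DiffResult", function(object) {
    sig <- object@groupStats[object@groupStats$significant, , drop = FALSE]
    cat("DiffResult:", length(unique(object@pairStats$protein)), "proteins,",
        nrow(unique(object@pairStats[, c("groupA", "groupB")])),
        "group pairs\n")
    if (nrow(sig)) {
        tab <- table(sig$group)
        cat("  significant proteins:",
            paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    } else cat("  significant proteins: none\n")
})

#' @describeIn DiffResult-class per-(protein, pair) G statistics table.
#' @param x a \code{DiffResult}.
#' @export
setMethod("pairStats", "DiffResult", function(x) x@pairStats)

#' @describeIn DiffResult-class per-(protein, group) significance table.
#' @export
setMethod("groupStats", "DiffResult", function(x) x@groupStats)
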