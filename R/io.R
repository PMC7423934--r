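## Tabular I/O. All artifacts are UTF-8 TSV with a mandatory header row and
## '.' decimal separator; run manifests are JSON; dendrograms export to
## Newick. Readers reject malformed numerics rather than coercing.

.read_tsv <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    if (file.size(path) == 0L) stop("empty file: ", path)
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, colClasses = "character",
                            na.strings = NULL, quote = "", comment.char = "")
    if (nrow(df) == 0L) stop("no data rows in ", path)
    df
}

## strict numeric parse; 'what' names the offending cell in the error
.as_number <- function(x, what) {
    suppressWarnings(v <- as.numeric(x))
    bad <- which(is.na(v) | !nzchar(trimws(x)))
    if (length(bad))
        stop("non-numeric value '", x[bad[1]], "' at ", what[bad[1]])
    v
}

#' Read a spectral-count matrix from TSV
#'
#' The first column holds protein identifiers; remaining columns hold
#' non-negative integral counts. With \code{replicateMode = "columns"},
#' column headers follow the \code{"sample.rep"} convention (text before
#' the first \code{.} is the sample) and several columns may map to one
#' sample.
#'
#' @param path TSV file path.
#' @param replicateMode \code{"none"} (one column per sample) or
#'   \code{"columns"}.
#' @return a [SpectralCountSet-class].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("protein\tS1.r1\tS1.r2\tS2.r1",
#'              "P1\t3\t4\t5", "P2\t0\t0\t2"), f)
#' scs <- readCountMatrix(f, replicateMode = "columns")
#' replicatesPerSample(scs)
#' @export
readCountMatrix <- function(path, replicateMode = c("none", "columns")) {
    replicateMode <- match.arg(replicateMode)
    df <- .read_tsv(path)
    if (ncol(df) < 2L) stop("count matrix needs >= 1 count column: ", path)
    ids <- df[[1L]]
    if (anyDuplicated(ids))
        stop("duplicate protein ids: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    cols <- colnames(df)[-1L]
    if (anyDuplicated(cols))
        stop("duplicate column names: ",
             paste(unique(cols[duplicated(cols)]), collapse = ", "))
    m <- matrix(0, nrow(df), length(cols), dimnames = list(ids, cols))
    for (j in seq_along(cols)) {
        v <- .as_number(df[[j + 1L]],
                        paste0("row '", ids, "', column '", cols[j], "'"))
        bad <- which(v < 0 | v != round(v))
        if (length(bad))
            stop("count must be a non-negative integer at row '",
                 ids[bad[1]], "', column '", cols[j], "' (got ",
                 df[[j + 1L]][bad[1]], ")")
        m[, j] <- v
    }
    if (replicateMode == "columns") {
        sample <- sub("\\..*$", "", cols)
        replicate <- ifelse(grepl("\\.", cols), sub("^[^.]*\\.", "", cols),
                            "r1")
        SpectralCountSet(m, sample = sample, replicate = replicate)
    } else {
        SpectralCountSet(m)
    }
}

#' Write a spectral-count or numeric matrix to TSV
#'
#' Inverse of [readCountMatrix()]: the round trip preserves values and the
#' order of ids exactly.
#'
#' @param x a [SpectralCountSet-class] or a matrix with dimnames.
#' @param path output TSV path.
#' @param idColumn header of the id column.
#' @return \code{path}, invisibly.
#' @export
writeCountMatrix <- function(x, path, idColumn = "protein") {
    m <- if (is(x, "SpectralCountSet")) counts(x) else as.matrix(x)
    df <- data.frame(id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df)[1L] <- idColumn
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Read sample metadata and build a group design
#'
#' @param path TSV with columns \code{sample_id} and \code{group}.
#' @param counts a [SpectralCountSet-class]; the metadata sample set must
#'   match its samples exactly.
#' @return a [GroupDesign-class] ordered as in \code{counts}.
#' @export
readSampleMetadata <- function(path, counts) {
    df <- .read_tsv(path)
    need <- c("sample_id", "group")
    if (!all(need %in% colnames(df)))
        stop("metadata needs columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(df$sample_id))
        stop("duplicate sample_id in metadata")
    want <- sampleIds(counts)
    extra <- setdiff(df$sample_id, want)
    miss <- setdiff(want, df$sample_id)
    if (length(extra) || length(miss))
        stop("sample mismatch between counts and metadata",
             if (length(miss)) paste0("; missing from metadata: ",
                                      paste(miss, collapse = ", ")),
             if (length(extra)) paste0("; not in counts: ",
                                       paste(extra, collapse = ", ")))
    idx <- match(want, df$sample_id)
    GroupDesign(df$sample_id[idx], df$group[idx])
}

#' Read a PPI edge list into an igraph
#'
#' Reads a TSV with columns \code{nodeA}, \code{nodeB} and optional
#' \code{score} in [0, 1] (e.g. a STRING export). Edges below
#' \code{scoreMin} are dropped at load; self-loops are dropped with a
#' warning; multi-edges collapse to one (keeping the maximum score).
#'
#' @param path TSV file path.
#' @param scoreMin minimum combined score to retain an edge; the STRING
#'   medium-confidence convention is 0.400.
#' @return an undirected simple \code{igraph} graph; retained scores sit in
#'   the \code{score} edge attribute when present in the file.
#' @export
readEdgeList <- function(path, scoreMin = 0) {
    stopifnot(scoreMin >= 0, scoreMin <= 1)
    df <- .read_tsv(path)
    if (!all(c("nodeA", "nodeB") %in% colnames(df)))
        stop("edge list needs columns nodeA, nodeB")
    bad <- which(!nzchar(df$nodeA) | !nzchar(df$nodeB))
    if (length(bad))
        stop("malformed edge row at line ", bad[1] + 1L)
    has_score <- "score" %in% colnames(df)
    if (has_score) {
        sc <- .as_number(df$score, paste0("line ", seq_len(nrow(df)) + 1L,
                                          ", column 'score'"))
        if (any(sc < 0 | sc > 1))
            stop("edge score outside [0,1] at line ",
                 which(sc < 0 | sc > 1)[1] + 1L)
        keep <- sc >= scoreMin
        df <- df[keep, , drop = FALSE]
        sc <- sc[keep]
    }
    loops <- df$nodeA == df$nodeB
    if (any(loops)) {
        warning(sum(loops), " self-loop(s) dropped")
        if (has_score) sc <- sc[!loops]
        df <- df[!loops, , drop = FALSE]
    }
    el <- cbind(df$nodeA, df$nodeB)
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    if (has_score) igraph::E(g)$score <- sc
    igraph::simplify(g, edge.attr.comb = list(score = "max", "ignore"))
}

#' Read a gene x sample copy-number matrix
#'
#' @param path TSV, first column gene id, remaining columns per-sample copy
#'   numbers (non-negative reals, 2 = diploid).
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
readCopyNumberMatrix <- function(path) {
    df <- .read_tsv(path)
    ids <- df[[1L]]
    if (anyDuplicated(ids)) stop("duplicate gene ids")
    smp <- colnames(df)[-1L]
    if (anyDuplicated(smp)) stop("duplicate sample ids")
    m <- matrix(0, nrow(df), length(smp), dimnames = list(ids, smp))
    for (j in seq_along(smp)) {
        v <- .as_number(df[[j + 1L]],
                        paste0("gene '", ids, "', sample '", smp[j], "'"))
        if (any(v < 0))
            stop("negative copy number at gene '", ids[which(v < 0)[1]],
                 "', sample '", smp[j], "'")
        m[, j] <- v
    }
    m
}

#' Read a somatic-mutation table
#'
#' @param path TSV with columns \code{sample_id}, \code{gene},
#'   \code{variant_class} and optional \code{protein_change}; \code{NULL}
#'   or a missing file yields an empty table.
#' @return data.frame with those columns.
#' @export
readMutationTable <- function(path = NULL) {
    empty <- data.frame(sample_id = character(), gene = character(),
                        variant_class = character(),
                        protein_change = character(),
                        stringsAsFactors = FALSE)
    if (is.null(path) || !file.exists(path)) return(empty)
    df <- .read_tsv(path)
    need <- c("sample_id", "gene", "variant_class")
    if (!all(need %in% colnames(df)))
        stop("mutation table needs columns: ", paste(need, collapse = ", "))
    if (!"protein_change" %in% colnames(df)) df$protein_change <- NA_character_
    df[, c(need, "protein_change")]
}

#' Read the genomic-alteration inputs together
#'
#' @param cnPath copy-number TSV (required).
#' @param mutPath mutation TSV (optional; missing gives an empty table).
#' @return list with elements \code{cn} (matrix) and \code{mutations}
#'   (data.frame).
#' @export
readGenomicTables <- function(cnPath, mutPath = NULL) {
    list(cn = readCopyNumberMatrix(cnPath),
         mutations = readMutationTable(mutPath))
}

#' Write a result table to TSV
#'
#' @param df a data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeResultTable <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Write a JSON run manifest
#'
#' Records parameters, seed and package version for machine-checkable
#' provenance of a pipeline run.
#'
#' @param path output JSON path.
#' @param params named list of parameters.
#' @param seed the seed used, or NA.
#' @return \code{path}, invisibly.
#' @export
writeRunManifest <- function(path, params = list(), seed = NA) {
    manifest <- list(
        package = "lepinet",
        version = as.character(utils::packageVersion("lepinet")),
        r_version = as.character(getRversion()),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        seed = seed,
        params = params)
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    invisible(path)
}

#' Export a dendrogram in Newick format
#'
#' @param hc an \code{hclust} tree (e.g. the \code{dendrogram} slot of a
#'   [CoexprModel-class]).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeDendrogramNewick <- function(hc, path) {
    stopifnot(inherits(hc, "hclust"))
    ape::write.tree(ape::as.phylo(hc), file = path)
    invisible(path)
}

#' Read a YAML configuration file
#'
#' Sections mirror module parameters (e.g. \code{gstat:}, \code{wgcna:});
#' values override function defaults in the command-line interface.
#'
#' @param path YAML file.
#' @return nested named list.
#' @export
readConfig <- function(path) yaml::read_yaml(path)

#' The 14-patient early lung adenocarcinoma cohort
#'
#' Clinical descriptors of the cohort the package's defaults emulate: five
#' adenocarcinoma in situ (AIS), five minimally invasive adenocarcinoma
#' (MIA) and four lepidic predominant invasive adenocarcinoma (LPA)
#' patients, with age, sex and tumour size on CT (mm).
#'
#' @return data.frame with columns sample_id, group, age, sex,
#'   tumour_size_mm.
#' @examples
#' coh <- luadCohort()
#' describeGroups(setNames(coh$age, coh$sample_id),
#'                GroupDesign(coh$sample_id, coh$group))
#' @export
luadCohort <- function() {
    path <- system.file("extdata", "luad_cohort.tsv", package = "lepinet",
                        mustWork = TRUE)
    df <- .read_tsv(path)
    df$age <- .as_number(df$age, paste0("row ", seq_len(nrow(df)), ", age"))
    df$tumour_size_mm <- .as_number(
        df$tumour_size_mm, paste0("row ", seq_len(nrow(df)), ", size"))
    df
}
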