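#' @importFrom BiocGenerics counts
#' @export
BiocGenerics::counts

#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @export
setGeneric("hasReplicates", function(x) standardGeneric("hasReplicates"))
#' @export
setGeneric("replicatesPerSample",
           function(x) standardGeneric("replicatesPerSample"))
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @export
setGeneric("groupAssignments", function(x) standardGeneric("groupAssignments"))
#' @export
setGeneric("groupLevels", function(x) standardGeneric("groupLevels"))
#' @export
setGeneric("groupSizes", function(x) standardGeneric("groupSizes"))
#' @export
setGeneric("traitVectors", function(x) standardGeneric("traitVectors"))
#' @export
setGeneric("normMethod", function(x) standardGeneric("normMethod"))
#' @export
setGeneric("moduleLabels", function(x) standardGeneric("moduleLabels"))
#' @export
setGeneric("eigenProteins", function(x) standardGeneric("eigenProteins"))
#' @export
setGeneric("traitStats", function(x) standardGeneric("traitStats"))
#' @export
setGeneric("pairStats", function(x) standardGeneric("pairStats"))
#' @export
setGeneric("groupStats", function(x) standardGeneric("groupStats"))
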