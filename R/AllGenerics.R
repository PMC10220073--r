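#' @include AllClasses.R
NULL

#' @export
setGeneric("motifId", function(x) standardGeneric("motifId"))

#' @export
setGeneric("motifWidth", function(x) standardGeneric("motifWidth"))

#' @export
setGeneric("motifCounts", function(x) standardGeneric("motifCounts"))

#' @export
setGeneric("motifBackground", function(x) standardGeneric("motifBackground"))

#' @export
setGeneric("logOdds", function(x) standardGeneric("logOdds"))

#' @export
setGeneric("maxScore", function(x) standardGeneric("maxScore"))

#' @export
setGeneric("minScore", function(x) standardGeneric("minScore"))

#' @export
setGeneric("shuffleColumns", function(x, seed) standardGeneric("shuffleColumns"))

#' @export
setGeneric("replicateCounts", function(x) standardGeneric("replicateCounts"))

#' @export
setGeneric("nullMu", function(x) standardGeneric("nullMu"))

#' @export
setGeneric("nullSigma", function(x) standardGeneric("nullSigma"))

#' @export
setGeneric("nReplicates", function(x) standardGeneric("nReplicates"))

#' @export
setGeneric("enrichTable", function(x) standardGeneric("enrichTable"))

#' @export
setGeneric("runMetadata", function(x) standardGeneric("runMetadata"))
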