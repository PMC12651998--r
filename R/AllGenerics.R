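#' @rdname GRN-accessors
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' @rdname GRN-accessors
#' @export
setGeneric("tfMask", function(x) standardGeneric("tfMask"))

#' @rdname GRN-accessors
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname GRN-accessors
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))

#' @rdname GRN-accessors
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))

#' @rdname GRN-accessors
#' @export
setGeneric("candidateMask", function(x) standardGeneric("candidateMask"))

#' @rdname NoiseSchedule-accessors
#' @export
setGeneric("nSteps", function(x) standardGeneric("nSteps"))

#' @rdname NoiseSchedule-accessors
#' @export
setGeneric("priorDelta", function(x) standardGeneric("priorDelta"))

#' @rdname NoiseSchedule-accessors
#' @export
setGeneric("priorMatrix", function(x) standardGeneric("priorMatrix"))

#' @rdname MetricReport-accessors
#' @export
setGeneric("reportTable", function(x) standardGeneric("reportTable"))

#' @rdname MetricReport-accessors
#' @export
setGeneric("reportMeans", function(x) standardGeneric("reportMeans"))
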