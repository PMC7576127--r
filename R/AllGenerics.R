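#' @rdname CalciumTrace-class
#' @param object,x a package object.
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname CalciumTrace-class
#' @export
setGeneric("traceValues", function(object) standardGeneric("traceValues"))

#' @rdname CalciumTrace-class
#' @export
setGeneric("startTime", function(object) standardGeneric("startTime"))

#' @rdname CalciumTrace-class
#' @export
setGeneric("frameTimes", function(object) standardGeneric("frameTimes"))

#' @rdname SpikeTrain-class
#' @param object a package object.
#' @export
setGeneric("spikeTimes", function(object) standardGeneric("spikeTimes"))

#' @rdname CandidateSet-class
#' @param object a \code{CandidateSet}.
#' @export
setGeneric("pseudoTimes", function(object) standardGeneric("pseudoTimes"))

#' @rdname CandidateSet-class
#' @export
setGeneric("candidateLabels",
           function(object) standardGeneric("candidateLabels"))
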