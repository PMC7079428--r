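#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @export
setGeneric("featureType", function(x) standardGeneric("featureType"))

#' @export
setGeneric("traitKind", function(x) standardGeneric("traitKind"))

#' @export
setGeneric("traitEncodings", function(x) standardGeneric("traitEncodings"))

#' @export
setGeneric("stateCodes", function(x) standardGeneric("stateCodes"))

#' @export
setGeneric("stateThresholdsOf", function(x) standardGeneric("stateThresholdsOf"))

#' @export
setGeneric("realizedFractions", function(x) standardGeneric("realizedFractions"))

#' @export
setGeneric("duoComponents", function(x) standardGeneric("duoComponents"))

#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @export
setGeneric("networkMetric", function(x) standardGeneric("networkMetric"))

#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
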