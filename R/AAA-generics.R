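#' @rdname EMGRecording-class
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @rdname EMGRecording-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname EMGRecording-class
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname EMGRecording-class
#' @export
setGeneric("schedule", function(x) standardGeneric("schedule"))

#' @rdname EMGRecording-class
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname EMGWindowSet-class
#' @export
setGeneric("windowData", function(x, i) standardGeneric("windowData"))

#' @rdname EMGWindowSet-class
#' @export
setGeneric("nWindows", function(x) standardGeneric("nWindows"))

#' @rdname EMGWindowSet-class
#' @export
setGeneric("windowLength", function(x) standardGeneric("windowLength"))

#' @rdname EMGWindowSet-class
#' @export
setGeneric("windowLabels", function(x) standardGeneric("windowLabels"))

#' @rdname EMGFeatureMatrix-class
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname EMGFeatureMatrix-class
#' @export
setGeneric("featureInfo", function(x) standardGeneric("featureInfo"))
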