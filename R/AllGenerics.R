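#' @rdname GridGeometry-class
#' @param object a `GridGeometry`
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))

#' @rdname GridRecording-class
#' @param object an object with voltage data
#' @export
setGeneric("voltages", function(object) standardGeneric("voltages"))

#' @rdname GridRecording-class
#' @export
setGeneric("sampleRate", function(object) standardGeneric("sampleRate"))

#' @rdname GridRecording-class
#' @export
setGeneric("stimulusEvents", function(object) standardGeneric("stimulusEvents"))

#' @rdname GridRecording-class
#' @export
setGeneric("recordingPhase", function(object) standardGeneric("recordingPhase"))

#' @rdname GridRecording-class
#' @export
setGeneric("geometry", function(object) standardGeneric("geometry"))

#' @rdname LayerMap-class
#' @param object a `LayerMap`
#' @export
setGeneric("layerLabels", function(object) standardGeneric("layerLabels"))

#' @rdname LayerMap-class
#' @export
setGeneric("network", function(object) standardGeneric("network"))

#' @rdname EvokedEpochSet-class
#' @param object an `EvokedEpochSet`
#' @export
setGeneric("epochArray", function(object) standardGeneric("epochArray"))

#' @rdname EvokedEpochSet-class
#' @export
setGeneric("epochTimeMs", function(object) standardGeneric("epochTimeMs"))

#' @rdname CSDMap-class
#' @param object a `CSDMap`
#' @export
setGeneric("csdValues", function(object) standardGeneric("csdValues"))
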