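#' Construct a grid recording
#'
#' @param voltages numeric matrix, channels x samples, microvolts.
#' @param rate sampling rate in Hz (platform default 14000).
#' @param geometry a [GridGeometry-class]; must match `nrow(voltages)`.
#' @param events stimulus event data frame (see [GridRecording-class]); a
#'   data frame with at least a `time` column — missing columns are filled
#'   with defaults (intensity 0, half-width 100 us, test pulses).
#' @param phase `"baseline"`, `"post_tetanic"` or `"io_sweep"`.
#' @param t0 trace start time, seconds.
#' @return a validated [GridRecording-class].
#' @export
gridRecording <- function(voltages, rate = 14000, geometry = NULL,
                          events = emptyEvents(), phase = "baseline", t0 = 0) {
  if (is.null(geometry)) {
    n <- as.integer(round(sqrt(nrow(voltages))))
    if (n * n != nrow(voltages))
      stopf("geometry not given and channel count %d is not square", nrow(voltages))
    geometry <- gridGeometry(n, n)
  }
  events <- completeEvents(events)
  new("GridRecording", voltages = voltages, rate = as.numeric(rate),
      geometry = geometry, events = events, phase = phase, t0 = as.numeric(t0))
}

completeEvents <- function(events) {
  if (is.null(events)) return(emptyEvents())
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  if (nrow(events) && !"time" %in% names(events))
    stopf("events must have a 'time' column")
  n <- nrow(events)
  defaults <- list(intensity = 0, half_width_us = 100, site_x = 0, site_y = 0,
                   kind = "test_pulse", nominal_min = NA_real_)
  for (nm in names(defaults))
    if (!nm %in% names(events)) events[[nm]] <- rep(defaults[[nm]], length.out = max(n, 0L))
  if (!"time" %in% names(events)) events$time <- numeric(0)
  events[, eventColumns, drop = FALSE]
}

#' @rdname GridRecording-class
#' @export
setMethod("voltages", "GridRecording", function(object) object@voltages)
#' @rdname GridRecording-class
#' @export
setMethod("sampleRate", "GridRecording", function(object) object@rate)
#' @rdname GridRecording-class
#' @export
setMethod("stimulusEvents", "GridRecording", function(object) object@events)
#' @rdname GridRecording-class
#' @export
setMethod("recordingPhase", "GridRecording", function(object) object@phase)
#' @rdname GridRecording-class
#' @export
setMethod("geometry", "GridRecording", function(object) object@geometry)

setMethod("show", "GridRecording", function(object) {
  cat(sprintf("GridRecording (%s): %d channels x %d samples @ %g Hz, %d events\n",
              object@phase, nrow(object@voltages), ncol(object@voltages),
              object@rate, nrow(object@events)))
})

#' Construct a layer map from explicit labels
#'
#' @param labels character or factor vector, one entry per electrode in
#'   row-major channel order; values from [LAYER_LEVELS].
#' @param network `"CA"`, `"DG"` or `"mixed"`.
#' @return a validated [LayerMap-class].
#' @seealso [makeLayerMap()] for the parametric band generator.
#' @export
layerMap <- function(labels, network) {
  labels <- factor(as.character(labels), levels = LAYER_LEVELS)
  new("LayerMap", labels = labels, network = network)
}

#' @rdname LayerMap-class
#' @export
setMethod("layerLabels", "LayerMap", function(object) object@labels)
#' @rdname LayerMap-class
#' @export
setMethod("network", "LayerMap", function(object) object@network)

setMethod("show", "LayerMap", function(object) {
  tab <- table(object@labels)
  tab <- tab[tab > 0]
  cat(sprintf("LayerMap (%s): %s\n", object@network,
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
})

#' @rdname EvokedEpochSet-class
#' @export
setMethod("epochArray", "EvokedEpochSet", function(object) object@epochs)
#' @rdname EvokedEpochSet-class
#' @export
setMethod("epochTimeMs", "EvokedEpochSet", function(object) object@timeMs)

setMethod("show", "EvokedEpochSet", function(object) {
  d <- dim(object@epochs)
  cat(sprintf("EvokedEpochSet (%s): %d electrodes x %d stimuli x %d samples (%.1f..%.1f ms)\n",
              object@phase, d[1], d[2], d[3], min(object@timeMs), max(object@timeMs)))
})

#' @rdname CSDMap-class
#' @export
setMethod("csdValues", "CSDMap", function(object) object@values)

setMethod("show", "CSDMap", function(object) {
  cat(sprintf("CSDMap: %d x %d grid, lambda = %g, basis width R = %g um\n",
              nrow(object@values), ncol(object@values), object@lambda, object@basisWidth))
})
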