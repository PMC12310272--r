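#' Anatomical layer codes
#'
#' Admissible per-electrode labels: CA strata (SO, SP, SR, SLM), dentate gyrus
#' laminae (ML, GCL, H), and `none` for electrodes outside any lamina.
#' @export
LAYER_LEVELS <- c("SO", "SP", "SR", "SLM", "ML", "GCL", "H", "none")

CA_LAYERS <- c("SO", "SP", "SR", "SLM")
DG_LAYERS <- c("ML", "GCL", "H")

PHASE_LEVELS <- c("baseline", "post_tetanic", "io_sweep")
EVENT_KINDS <- c("test_pulse", "hfs_train")

eventColumns <- c("time", "intensity", "half_width_us", "site_x", "site_y",
                  "kind", "nominal_min")

emptyEvents <- function() {
  data.frame(time = numeric(0), intensity = numeric(0),
             half_width_us = numeric(0), site_x = numeric(0),
             site_y = numeric(0), kind = character(0),
             nominal_min = numeric(0), stringsAsFactors = FALSE)
}

#' GridGeometry: planar electrode grid
#'
#' Describes the regular electrode grid of a high-density CMOS MEA:
#' `nRows` x `nCols` electrodes at `pitch` micrometres. Channels are numbered
#' row-major with channel 1 at grid position (row 1, col 1); electrode
#' coordinates in micrometres are `x = (col-1)*pitch`, `y = (row-1)*pitch`
#' with the origin at the top-left electrode.
#'
#' @slot nRows,nCols integer grid extent (default platform: 64 x 64).
#' @slot pitch electrode pitch in micrometres (default platform: 42).
#' @export
setClass("GridGeometry",
  representation(nRows = "integer", nCols = "integer", pitch = "numeric"),
  prototype(nRows = 64L, nCols = 64L, pitch = 42))

setValidity("GridGeometry", function(object) {
  if (length(object@nRows) != 1L || object@nRows < 1L) return("nRows must be a positive integer")
  if (length(object@nCols) != 1L || object@nCols < 1L) return("nCols must be a positive integer")
  if (length(object@pitch) != 1L || !is.finite(object@pitch) || object@pitch <= 0)
    return("pitch must be a positive length in micrometres")
  TRUE
})

#' GridRecording: multichannel voltage time series on an electrode grid
#'
#' Voltages are stored channels x samples in microvolts at sampling rate
#' `rate` (Hz). `events` is a data frame of stimulus events with columns
#' `time` (s, within the trace), `intensity` (uA), `half_width_us`,
#' `site_x`/`site_y` (um), `kind` (`test_pulse` or `hfs_train`) and
#' `nominal_min` (protocol time in minutes relative to HFS onset; recordings
#' may store a thinned subset of the nominal test-pulse schedule, so trace
#' time and protocol time are kept separately).
#'
#' @slot voltages numeric matrix \[channels x samples\], microvolts.
#' @slot rate sampling rate in Hz.
#' @slot geometry a [GridGeometry-class].
#' @slot events stimulus event table (see above).
#' @slot phase one of `baseline`, `post_tetanic`, `io_sweep`.
#' @slot t0 trace start time in seconds.
#' @export
setClass("GridRecording",
  representation(voltages = "matrix", rate = "numeric", geometry = "GridGeometry",
                 events = "data.frame", phase = "character", t0 = "numeric"))

setValidity("GridRecording", function(object) {
  g <- object@geometry
  nchan <- g@nRows * g@nCols
  if (nrow(object@voltages) != nchan)
    return(sprintf("voltages has %d rows but geometry implies %d channels",
                   nrow(object@voltages), nchan))
  if (length(object@rate) != 1L || object@rate <= 0) return("rate must be > 0")
  if (!.cpp_all_finite(object@voltages)) return("voltages must be finite")
  if (!all(object@phase %in% PHASE_LEVELS) || length(object@phase) != 1L)
    return(sprintf("phase must be one of %s", paste(PHASE_LEVELS, collapse = ", ")))
  ev <- object@events
  if (!all(eventColumns %in% names(ev))) return("events is missing required columns")
  if (nrow(ev)) {
    if (!all(ev$kind %in% EVENT_KINDS)) return("unknown event kind")
    tEnd <- object@t0 + ncol(object@voltages) / object@rate
    if (any(ev$time < object@t0 - 1e-12) || any(ev$time > tEnd + 1e-12))
      return("event time outside the recorded trace")
    if (any(ev$intensity < 0)) return("event intensity must be >= 0")
    hw <- ev$half_width_us
    if (any(hw < 70 | hw > 140))
      return("pulse half-width outside the admissible 70-140 us range")
  }
  TRUE
})

#' LayerMap: per-electrode anatomical labels
#'
#' One label per electrode (row-major channel order), drawn from
#' [LAYER_LEVELS]. CA networks use only SO/SP/SR/SLM/none, DG networks only
#' ML/GCL/H/none.
#'
#' @slot labels factor of length `nRows * nCols` with levels [LAYER_LEVELS].
#' @slot network `"CA"`, `"DG"`, or `"mixed"`.
#' @export
setClass("LayerMap",
  representation(labels = "factor", network = "character"))

setValidity("LayerMap", function(object) {
  if (!identical(levels(object@labels), LAYER_LEVELS))
    return("labels must be a factor with levels LAYER_LEVELS")
  if (anyNA(object@labels)) return("every electrode needs a label (use 'none')")
  if (length(object@network) != 1L || !object@network %in% c("CA", "DG", "mixed"))
    return("network must be 'CA', 'DG' or 'mixed'")
  used <- unique(as.character(object@labels))
  if (object@network == "CA" && !all(used %in% c(CA_LAYERS, "none")))
    return("CA networks admit only SO/SP/SR/SLM/none labels")
  if (object@network == "DG" && !all(used %in% c(DG_LAYERS, "none")))
    return("DG networks admit only ML/GCL/H/none labels")
  TRUE
})

#' EvokedEpochSet: stimulus-aligned waveform windows
#'
#' Array of per-electrode, per-stimulus voltage windows aligned to stimulus
#' onset. `timeMs` is the epoch time axis in milliseconds relative to onset
#' (includes 0); after [blankAndCenter()] the pre-stimulus mean of every epoch
#' is zero.
#'
#' @slot epochs numeric array \[electrodes x stimuli x samples\], microvolts.
#' @slot timeMs epoch time axis, ms relative to stimulus onset.
#' @slot rate sampling rate in Hz.
#' @slot events the test-pulse events the epochs were cut around.
#' @slot phase recording phase tag.
#' @slot provenance list: preprocessing config and processing flags.
#' @export
setClass("EvokedEpochSet",
  representation(epochs = "array", timeMs = "numeric", rate = "numeric",
                 events = "data.frame", phase = "character",
                 provenance = "list"))

setValidity("EvokedEpochSet", function(object) {
  d <- dim(object@epochs)
  if (length(d) != 3L) return("epochs must be a 3-d array [electrodes x stimuli x samples]")
  if (d[3] != length(object@timeMs)) return("timeMs length must match sample dimension")
  if (!any(abs(object@timeMs) < 1e-9)) return("epoch time axis must include 0")
  if (d[2] != nrow(object@events)) return("one event per epoch required")
  TRUE
})

#' CSDMap: estimated current source density on a spatial grid
#'
#' Sign convention: negative values are sinks (net inward transmembrane
#' current, EPSP-associated), positive values are sources. Metadata records
#' the regularization and basis parameters used for the estimate.
#'
#' @slot values numeric matrix \[grid rows x grid cols\], CSD in arbitrary
#'   units proportional to current per volume.
#' @slot lambda ridge regularization used.
#' @slot basisWidth Gaussian basis width R in micrometres.
#' @slot meta list: estimation grid coordinates, forward-model parameters,
#'   the sample/timestamp the map refers to.
#' @export
setClass("CSDMap",
  representation(values = "matrix", lambda = "numeric", basisWidth = "numeric",
                 meta = "list"))

setValidity("CSDMap", function(object) {
  if (!all(is.finite(object@values))) return("CSD values must be finite")
  if (object@lambda < 0) return("lambda must be >= 0")
  if (object@basisWidth <= 0) return("basis width must be > 0")
  TRUE
})
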