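#' On-disk session container
#'
#' Recordings are stored as a directory: `meta.json` carries all metadata
#' (schema version, rate, geometry, phase, events, layer labels, optional
#' ground truth) and each voltage matrix is a raw little-endian float64
#' file (`<name>.f64`, column-major, channels x samples, microvolts), so
#' integers and enums round-trip bit-exactly and voltages at full double
#' precision. The schema (dataset names, dtypes, units) is documented in
#' `inst/schema/container.md`.
#'
#' @param recording a [GridRecording-class].
#' @param layers a [LayerMap-class].
#' @param path directory to create/overwrite.
#' @param truth optional `GroundTruth` to embed.
#' @return `path`, invisibly.
#' @name container
NULL

CONTAINER_SCHEMA_VERSION <- "1.0"

recordingMeta <- function(recording) {
  g <- geometry(recording)
  list(rate = sampleRate(recording), t0 = recording@t0,
       phase = recordingPhase(recording),
       n_rows = g@nRows, n_cols = g@nCols, pitch_um = g@pitch,
       n_samples = ncol(voltages(recording)),
       events = stimulusEvents(recording))
}

writeVoltages <- function(vol, file) {
  con <- file(file, "wb")
  on.exit(close(con))
  writeBin(as.vector(vol), con, size = 8L, endian = "little")
}

readVoltages <- function(file, nchan, nsamp) {
  if (!file.exists(file)) stopf("container schema error: missing dataset %s", file)
  expect <- nchan * nsamp * 8
  if (file.info(file)$size != expect)
    stopf("container schema error: %s has %d bytes, expected %d (truncated or wrong shape)",
          file, file.info(file)$size, expect)
  con <- file(file, "rb")
  on.exit(close(con))
  matrix(readBin(con, "double", nchan * nsamp, size = 8L, endian = "little"),
         nchan, nsamp)
}

#' @rdname container
#' @export
saveRecording <- function(recording, layers, path, truth = NULL) {
  stopifnot(is(recording, "GridRecording"), is(layers, "LayerMap"))
  validObject(recording); validObject(layers)
  if (length(layerLabels(layers)) != nrow(voltages(recording)))
    stopf("validation error: layer map has %d labels for %d channels",
          length(layerLabels(layers)), nrow(voltages(recording)))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(schema_version = CONTAINER_SCHEMA_VERSION,
               recording = recordingMeta(recording),
               layers = list(labels = as.character(layerLabels(layers)),
                             network = network(layers)),
               ground_truth = if (!is.null(truth)) unclass(truth))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "columns", pretty = TRUE)
  writeVoltages(voltages(recording), file.path(path, "voltages.f64"))
  invisible(path)
}

parseEvents <- function(ev) {
  if (is.null(ev) || !length(ev$time)) return(emptyEvents())
  out <- as.data.frame(lapply(ev, function(col) {
    col[vapply(col, is.null, logical(1))] <- NA
    unlist(col)
  }), stringsAsFactors = FALSE)
  for (nm in setdiff(names(out), "kind")) out[[nm]] <- as.numeric(out[[nm]])
  out
}

#' @rdname container
#' @export
loadRecording <- function(path) {
  metaFile <- file.path(path, "meta.json")
  if (!file.exists(metaFile)) stopf("container schema error: no meta.json in %s", path)
  meta <- jsonlite::read_json(metaFile, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  ver <- meta$schema_version
  if (is.null(ver)) stopf("container schema error: no schema_version field")
  if (!identical(ver, CONTAINER_SCHEMA_VERSION))
    stopf("unknown container schema version '%s' (this build reads %s)",
          ver, CONTAINER_SCHEMA_VERSION)
  rm <- meta$recording
  g <- gridGeometry(rm$n_rows, rm$n_cols, rm$pitch_um)
  vol <- readVoltages(file.path(path, "voltages.f64"), nChannels(g), rm$n_samples)
  rec <- gridRecording(vol, rate = rm$rate, geometry = g,
                       events = parseEvents(rm$events),
                       phase = rm$phase, t0 = rm$t0)
  if (is.null(meta$layers) || is.null(meta$layers$labels))
    stopf("container schema error: missing /layers (per-electrode labels)")
  lay <- layerMap(unlist(meta$layers$labels), meta$layers$network)
  truth <- meta$ground_truth
  if (!is.null(truth)) {
    truth$electrodes <- as.data.frame(lapply(truth$electrodes, unlist),
                                      stringsAsFactors = FALSE)
    truth$clusters <- as.data.frame(lapply(truth$clusters, unlist),
                                    stringsAsFactors = FALSE)
    class(truth) <- c("GroundTruth", "list")
  }
  list(recording = rec, layers = lay, truth = truth)
}

#' Save or load a complete simulated session
#'
#' A session directory holds one recording container per generated phase
#' (`io_sweep/`, `baseline/`, `post_tetanic/`) plus the shared layer map
#' and ground truth (stored with the first phase).
#'
#' @param session an `LtpSession` from [simulateSession()].
#' @param path session directory.
#' @return `loadSession`: an `LtpSession`-shaped list.
#' @export
saveSession <- function(session, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  first <- TRUE
  for (ph in c("io_sweep", "baseline", "post_tetanic")) {
    if (is.null(session[[ph]])) next
    saveRecording(session[[ph]], session$layers, file.path(path, ph),
                  truth = if (first) session$truth)
    first <- FALSE
  }
  invisible(path)
}

#' @rdname saveSession
#' @export
loadSession <- function(path) {
  out <- list(io_sweep = NULL, baseline = NULL, post_tetanic = NULL,
              layers = NULL, truth = NULL)
  found <- FALSE
  for (ph in c("io_sweep", "baseline", "post_tetanic")) {
    d <- file.path(path, ph)
    if (!dir.exists(d)) next
    r <- loadRecording(d)
    out[[ph]] <- r$recording
    out$layers <- out$layers %||% r$layers
    out$truth <- out$truth %||% r$truth
    found <- TRUE
  }
  if (!found) stopf("no recording containers under %s", path)
  out$network <- network(out$layers)
  structure(out, class = c("LtpSession", "list"))
}
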