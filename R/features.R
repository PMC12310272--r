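#' Extract waveform features per electrode
#'
#' Computes, on the per-electrode mean evoked waveform: peak-to-peak
#' amplitude (uV), maximum rising slope (uV/ms, magnitude of the steepest
#' smoothed first difference between epoch start and the global extremum),
#' and peak latency (ms of the global absolute extremum after the blank
#' window). An electrode is active iff its mean waveform exceeds
#' `activityThresholdSd` standard errors of the mean at some post-stimulus
#' sample, where the standard error comes from the across-trial variance
#' (smoothed along the time axis). Band-passed noise is autocorrelated and
#' wanders relative to the pre-stimulus anchor, so a short pre-window SD
#' would underestimate the null variability; the across-trial spread
#' measures it directly. The default threshold (6) keeps the familywise
#' false-activation rate across the ~1400 scanned samples per electrode
#' negligible given the statistic's t-like tails. Inactive electrodes get
#' zero features. With a single epoch the pre-window SD is used as a
#' fallback.
#'
#' For classification, each active electrode's mean waveform is also
#' extracted in a window of `alignWindowMs` around its own extremum
#' (zero-padded at epoch edges), so the appended waveform vector reflects
#' shape rather than propagation latency; latency itself stays available as
#' a scalar feature.
#'
#' @param epochs a blanked, centered [EvokedEpochSet-class].
#' @param activityThresholdSd activity threshold in pre-stimulus SD units.
#' @param alignWindowMs length-2 numeric, peak-aligned waveform window (ms
#'   around the extremum).
#' @param smoothSamples moving-average width (samples) for the slope.
#' @return a `WaveformFeatureTable`: list with `features` (data frame:
#'   `channel`, `p2pUv`, `slopeUvMs`, `latencyMs`, `amplitudeUv`, `active`),
#'   `waveforms` (peak-aligned matrix, active electrodes only), `phase`.
#' @export
extractFeatures <- function(epochs, activityThresholdSd = 6,
                            alignWindowMs = c(-10, 25), smoothSamples = 5) {
  stopifnot(is(epochs, "EvokedEpochSet"))
  if (!isTRUE(epochs@provenance$centered))
    stopf("epochs must be blanked and centered first (see blankAndCenter)")
  cfg <- epochs@provenance$config
  tm <- epochs@timeMs
  post <- which(tm > cfg$blankMs)
  pre <- which(tm < 0)
  d <- dim(epochs@epochs)
  # Mean waveform plus the activity statistic: |mean| in units of its
  # standard error from the across-trial variance (smoothed along time).
  # Band-passed noise is autocorrelated within an epoch and wanders
  # relative to the pre-stimulus anchor, so a short pre-window SD would
  # underestimate the null variability; the trial-to-trial spread at each
  # sample measures it directly.
  st <- .cpp_activity_stat(epochs@epochs, d, tm, cfg$blankMs, 201L)
  mw <- st$mw
  pkIdx <- st$pkIdx
  ext <- st$ext
  active <- if (d[2] >= 2) {
    st$maxStat > activityThresholdSd
  } else {
    preSd <- apply(mw[, pre, drop = FALSE], 1, stats::sd)
    abs(ext) > activityThresholdSd * preSd
  }

  mm <- .cpp_row_minmax(mw, post[1], post[length(post)])
  p2p <- mm$max - mm$min

  # steepest smoothed first difference from epoch start to the extremum
  dtMs <- 1000 / epochs@rate
  slope <- numeric(nrow(mw))
  rowsAct <- which(active)
  if (length(rowsAct)) {
    sm <- movingAverageRows(mw[rowsAct, , drop = FALSE], smoothSamples)
    for (j in seq_along(rowsAct)) {
      dv <- diff(sm[j, seq_len(pkIdx[rowsAct[j]])]) / dtMs
      slope[rowsAct[j]] <- if (length(dv)) max(abs(dv)) else 0
    }
  }

  lat <- ifelse(active, tm[pkIdx], NA_real_)
  feat <- data.frame(channel = seq_len(nrow(mw)),
                     p2pUv = ifelse(active, p2p, 0),
                     slopeUvMs = slope,
                     latencyMs = lat,
                     amplitudeUv = ifelse(active, ext, 0),
                     active = active)

  aw <- round(alignWindowMs / dtMs)
  idxRel <- aw[1]:aw[2]
  wf <- matrix(0, sum(active), length(idxRel))
  rows <- which(active)
  for (j in seq_along(rows)) {
    e <- rows[j]
    src <- pkIdx[e] + idxRel
    ok <- src >= 1 & src <= ncol(mw)
    wf[j, ok] <- mw[e, src[ok]]
  }
  rownames(wf) <- rows
  structure(list(features = feat, waveforms = wf, phase = epochs@phase,
                 activityThresholdSd = activityThresholdSd),
            class = c("WaveformFeatureTable", "list"))
}

# centred moving average along rows (shorter at the edges), vectorized
movingAverageRows <- function(x, width) {
  if (width <= 1) return(x)
  half <- (width - 1) %/% 2
  cs <- cbind(0, t(apply(x, 1, cumsum)))
  n <- ncol(x)
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + (width - 1 - half), n)
  (cs[, hi + 1, drop = FALSE] - cs[, lo, drop = FALSE]) /
    matrix(hi - lo + 1, nrow(x), n, byrow = TRUE)
}
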