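#' fEPSP slope of a single epoch
#'
#' Magnitude of the linear least-squares slope fitted over the 20-80%
#' amplitude span of the initial rising phase of the dominant deflection
#' (the global absolute extremum after the blank window).
#'
#' @param wave numeric vector, one blanked/centered epoch (uV).
#' @param timeMs epoch time axis (ms relative to stimulus onset).
#' @param blankMs blank window to skip, ms.
#' @return slope in uV/ms (>= 0); 0 with attribute `flagged = TRUE` for a
#'   flat (inactive) epoch.
#' @export
fepspSlope <- function(wave, timeMs, blankMs = 2) {
  flat <- max(abs(wave[timeMs > blankMs])) == 0
  s <- .cpp_slope_rows(matrix(wave, 1), as.numeric(timeMs), blankMs)[1]
  if (flat) structure(0, flagged = TRUE) else s
}

#' Per-pulse fEPSP slopes for a set of electrodes
#'
#' The 20-80% fit window is determined once per electrode on its mean
#' evoked waveform, then each pulse's slope is a least-squares fit over
#' that fixed window. Fixing the window keeps the per-pulse estimator
#' unbiased under additive noise (selecting the span on each noisy epoch
#' attenuates slopes); on noise-free epochs it coincides with
#' [fepspSlope()] applied per epoch.
#'
#' @param epochs a blanked, centered [EvokedEpochSet-class].
#' @param channels electrode indices (default all).
#' @param blankMs blank window, ms.
#' @return matrix \[length(channels) x stimuli\] of slopes (uV/ms).
#' @export
epochSlopes <- function(epochs, channels = NULL, blankMs = NULL) {
  stopifnot(is(epochs, "EvokedEpochSet"))
  blankMs <- blankMs %||% epochs@provenance$config$blankMs
  arr <- epochs@epochs
  channels <- channels %||% seq_len(dim(arr)[1])
  out <- .cpp_epoch_slopes(arr, dim(arr), as.integer(channels),
                           epochs@timeMs, blankMs)
  rownames(out) <- channels
  out
}

#' Select the calibration intensity from an input/output curve
#'
#' The selected intensity is the tested intensity whose mean fEPSP slope is
#' nearest to `fraction` times the maximum slope (ties resolved to the lower
#' intensity).
#'
#' @param intensities tested intensities, uA, strictly increasing.
#' @param slopes mean fEPSP slope per intensity, uV/ms.
#' @param fraction target fraction of the maximum slope (default 0.6).
#' @param noiseFloor slopes <= this are considered noise; a curve whose
#'   maximum does not exceed it fails calibration.
#' @return an `IOCurve`: list with `intensities`, `slopes`,
#'   `selectedIntensity`, `targetSlope`.
#' @export
selectIntensity <- function(intensities, slopes, fraction = 0.6,
                            noiseFloor = 0) {
  if (length(intensities) != length(slopes)) stopf("length mismatch")
  if (any(diff(intensities) <= 0)) stopf("intensities must be strictly increasing")
  if (!any(is.finite(slopes)) || max(slopes, na.rm = TRUE) <= noiseFloor)
    stopf("calibration failure: flat input/output curve (max slope <= noise floor)")
  target <- fraction * max(slopes, na.rm = TRUE)
  sel <- which.min(abs(slopes - target))    # first = lowest intensity on ties
  structure(list(intensities = intensities, slopes = slopes,
                 selectedIntensity = intensities[sel], targetSlope = target),
            class = c("IOCurve", "list"))
}

#' Calibrate the test-pulse intensity from an I/O sweep recording
#'
#' Filters, epochs and blanks the sweep, computes mean fEPSP slopes over the
#' region of interest per tested intensity, and applies [selectIntensity()].
#'
#' @param ioRecording the `io_sweep` [GridRecording-class] (one test pulse
#'   per intensity step).
#' @param protocol a [protocolConfig()] (supplies `calibFraction`).
#' @param cfg a [preprocessConfig()].
#' @param roi electrode indices to average over; default: electrodes active
#'   on the sweep's mean waveforms.
#' @return an `IOCurve` (see [selectIntensity()]).
#' @export
calibrate <- function(ioRecording, protocol = protocolConfig(),
                      cfg = preprocessConfig(), roi = NULL) {
  stopifnot(recordingPhase(ioRecording) == "io_sweep")
  ep <- blankAndCenter(extractEpochs(bandpassFilter(ioRecording, cfg), cfg), cfg)
  if (is.null(roi)) {
    ft <- extractFeatures(ep)$features
    roi <- ft$channel[ft$active]
    if (!length(roi)) stopf("calibration failure: no active electrodes in the sweep")
  }
  sl <- epochSlopes(ep, roi)
  selectIntensity(ep@events$intensity, colMeans(sl), protocol$calibFraction)
}

#' Normalized potentiation time course
#'
#' Per-pulse fEPSP slopes of every electrode active (and labelled) at
#' baseline, normalized to that electrode's baseline mean slope (baseline
#' mean = 100% by construction). Electrodes silent at baseline are excluded
#' (they enter only the recruitment statistics); electrodes with a baseline
#' mean slope of ~0 are excluded and listed.
#'
#' @param baseEpochs,postEpochs blanked, centered [EvokedEpochSet-class]s
#'   for the two phases.
#' @param layers a [LayerMap-class].
#' @param activityThresholdSd baseline activity threshold.
#' @param features optionally, a precomputed `WaveformFeatureTable` for the
#'   baseline epochs.
#' @return a `PotentiationTimecourse`: list with `channel`, `layer`,
#'   `timeMinBase`, `timeMinPost` (protocol minutes relative to HFS),
#'   `normBase`, `normPost` (percent-of-baseline matrices), `aggregate`
#'   (data frame `phase`, `timeMin`, `layer`, `pct`), `excluded`.
#' @export
potentiationTimecourse <- function(baseEpochs, postEpochs, layers,
                                   activityThresholdSd = 6, features = NULL) {
  lab <- as.character(layerLabels(layers))
  ft <- (features %||% extractFeatures(baseEpochs, activityThresholdSd))$features
  ch <- ft$channel[ft$active & lab != "none"]
  if (!length(ch)) stopf("no active labelled electrodes at baseline")
  sl <- pairedPhaseSlopes(baseEpochs, postEpochs, ch)
  slB <- sl$base
  slP <- sl$post
  baseMean <- rowMeans(slB)
  bad <- baseMean <= 1e-9
  if (any(bad)) {
    message(sum(bad), " electrode(s) excluded: baseline mean slope ~ 0")
    ch <- ch[!bad]; slB <- slB[!bad, , drop = FALSE]
    slP <- slP[!bad, , drop = FALSE]; baseMean <- baseMean[!bad]
  }
  normB <- 100 * slB / baseMean
  # First-order correction of the ratio estimator: with finitely many
  # baseline pulses, E[1/mean(slB)] = (1/B)(1 + var(B_hat)/B^2) inflates
  # post/baseline ratios. var(B_hat) is estimated by contiguous split
  # halves, which stays valid when band-passed noise is correlated across
  # neighbouring pulses (a pooled per-pulse variance is not). Noise-free
  # sessions are unaffected (the halves agree exactly).
  nB <- ncol(slB)
  if (nB >= 2) {
    h <- nB %/% 2
    d <- rowMeans(slB[, seq_len(h), drop = FALSE]) -
      rowMeans(slB[, (h + 1):nB, drop = FALSE])
    corr <- pmax(1 - (d / (2 * baseMean))^2, 0.5)
  } else corr <- 1
  normP <- 100 * slP / baseMean * corr
  tB <- baseEpochs@events$nominal_min
  tP <- postEpochs@events$nominal_min
  layer <- lab[ch]
  agg <- rbind(
    aggregateByLayer(normB, layer, tB, "baseline"),
    aggregateByLayer(normP, layer, tP, "post_tetanic"))
  structure(list(channel = ch, layer = layer, timeMinBase = tB,
                 timeMinPost = tP, normBase = normB, normPost = normP,
                 aggregate = agg, excluded = which(bad)),
            class = c("PotentiationTimecourse", "list"))
}

# 20-80% rising-span sample indices of one waveform (thresholds located on
# the 5-sample-smoothed trace, mirroring the compiled slope kernel)
selectSpan <- function(v, tm, blankMs) {
  post <- which(tm > blankMs)
  x <- v[post]
  n <- length(x)
  cs <- cumsum(x)
  lo <- pmax(seq_len(n) - 2L, 1L); hi <- pmin(seq_len(n) + 2L, n)
  sm <- (cs[hi] - c(0, cs)[lo]) / (hi - lo + 1)
  pk <- which.max(abs(sm))
  A <- abs(sm[pk])
  if (A == 0) return(NULL)
  below <- which(abs(sm[seq_len(pk)]) < 0.2 * A)
  i20 <- if (length(below)) max(below) else 0L
  idx <- (i20 + 1L):pk
  sel <- idx[abs(sm[idx]) >= 0.2 * A & abs(sm[idx]) <= 0.8 * A]
  if (length(sel) < 2L) {
    if (pk < 2L) return(NULL)
    sel <- c(pk - 1L, pk)
  }
  post[sel]
}

#' Per-pulse fEPSP slopes of two phases over a common waveform window
#'
#' Slopes for the baseline and post-tetanic epochs of the same electrodes,
#' with the 20-80% fit window determined once per electrode and reused in
#' both phases after compensating the post-tetanic latency shift
#' (estimated by cross-correlating the two mean waveforms). Fitting both
#' phases over the same waveform-relative samples makes the post/baseline
#' slope ratio exact for every realized window, eliminating the
#' phase-asymmetric window-selection bias of independent per-phase spans.
#'
#' @param baseEpochs,postEpochs blanked, centered [EvokedEpochSet-class]s.
#' @param channels electrode indices.
#' @return list with `base` and `post` slope matrices
#'   (\[channels x pulses\], uV/ms) and `shiftSamples` per electrode.
#' @export
pairedPhaseSlopes <- function(baseEpochs, postEpochs, channels) {
  blank <- baseEpochs@provenance$config$blankMs
  tmB <- baseEpochs@timeMs; tmP <- postEpochs@timeMs
  arrB <- baseEpochs@epochs; arrP <- postEpochs@epochs
  rate <- baseEpochs@rate
  mwOf <- function(arr) {
    out <- matrix(0, length(channels), dim(arr)[3])
    for (k in seq_len(dim(arr)[2])) out <- out + arr[channels, k, ]
    out / dim(arr)[2]
  }
  mwB <- mwOf(arrB)
  mwP <- mwOf(arrP)
  # latency shift per electrode: difference of the half-amplitude rising
  # crossings (sub-sample interpolated on the smoothed mean waveform) -- a
  # steep-slope feature, far more shift-sensitive than peak position or
  # cross-correlation maxima
  post <- which(tmB > blank)
  t50 <- function(v) {
    x <- v[post]
    n <- length(x)
    cs <- cumsum(x)
    lo <- pmax(seq_len(n) - 2L, 1L); hi <- pmin(seq_len(n) + 2L, n)
    sm <- (cs[hi] - c(0, cs)[lo]) / (hi - lo + 1)
    pk <- which.max(abs(sm))
    A <- abs(sm[pk]); if (A == 0) return(NA_real_)
    sgn <- sign(sm[pk])
    below <- which(sgn * sm[seq_len(pk)] < 0.5 * A)
    i <- if (length(below)) max(below) else return(pk)
    if (i == pk) return(pk)
    frac <- (0.5 * A - sgn * sm[i]) / (sgn * sm[i + 1] - sgn * sm[i])
    i + max(min(frac, 1), 0)
  }
  shift <- vapply(seq_along(channels), function(j)
    round(t50(mwP[j, ]) - t50(mwB[j, ])), numeric(1))
  shift[!is.finite(shift)] <- 0
  nB <- dim(arrB)[2]; nP <- dim(arrP)[2]
  slB <- matrix(0, length(channels), nB)
  slP <- matrix(0, length(channels), nP)
  fit <- function(Y, x) {
    xc <- x - mean(x)
    abs(as.numeric(Y %*% xc) / sum(xc^2))
  }
  for (j in seq_along(channels)) {
    # window from the shift-aligned, per-phase-normalized average waveform
    idx <- seq_along(tmB)
    src <- idx + shift[j]
    ok <- src >= 1 & src <= length(tmP)
    aligned <- numeric(length(tmB))
    aligned[idx[ok]] <- mwP[j, src[ok]]          # mwP shifted back into base frame
    sB <- max(abs(mwB[j, post])); sP <- max(abs(aligned[post]))
    comb <- (if (sB > 0) mwB[j, ] / sB else 0) +
      (if (sP > 0) aligned / sP else 0)
    sel <- selectSpan(comb, tmB, blank)
    if (is.null(sel)) next
    selP <- sel + shift[j]
    if (min(selP) < 1 || max(selP) > length(tmP) || any(tmP[selP] <= blank)) {
      selP <- selectSpan(mwP[j, ], tmP, blank)
      if (is.null(selP)) next
    }
    slB[j, ] <- fit(arrB[channels[j], , sel, drop = FALSE][1, , ], tmB[sel])
    slP[j, ] <- fit(arrP[channels[j], , selP, drop = FALSE][1, , ], tmP[selP])
  }
  rownames(slB) <- rownames(slP) <- channels
  list(base = slB, post = slP, shiftSamples = shift)
}

aggregateByLayer <- function(norm, layer, timeMin, phase) {
  layers <- sort(unique(layer))
  do.call(rbind, lapply(layers, function(l) {
    data.frame(phase = phase, timeMin = timeMin, layer = l,
               pct = colMeans(norm[layer == l, , drop = FALSE]))
  }))
}

#' Detect LTP and its onset per layer
#'
#' LTP is flagged when the mean normalized response over the first
#' `evalWindowMin` minutes post-HFS is at least `ltpThresholdPct` percent
#' above baseline (inclusive). Onset is the first post-HFS time at which the
#' 5-pulse moving average of the layer aggregate crosses the threshold.
#'
#' @param tc a `PotentiationTimecourse`.
#' @param protocol a [protocolConfig()] (supplies `ltpThresholdPct`).
#' @param evalWindowMin evaluation window for the flag, minutes.
#' @return data frame: `layer`, `meanPct` (evaluation-window mean), `ltp`
#'   (logical), `onsetMin` (NA when never crossed).
#' @export
detectLtp <- function(tc, protocol = protocolConfig(), evalWindowMin = 60) {
  thr <- 100 + protocol$ltpThresholdPct
  post <- tc$aggregate[tc$aggregate$phase == "post_tetanic", ]
  layers <- unique(post$layer)
  res <- lapply(layers, function(l) {
    s <- post[post$layer == l, ]
    s <- s[order(s$timeMin), ]
    inWin <- s$timeMin <= evalWindowMin
    m <- mean(s$pct[inWin])
    ma <- vapply(seq_len(nrow(s)), function(i)
      mean(s$pct[max(1, i - 4):i]), numeric(1))
    eps <- 1e-9 * thr                  # keep the >= threshold inclusive
    cross <- which(ma >= thr - eps)
    data.frame(layer = l, meanPct = m, ltp = m >= thr - eps,
               onsetMin = if (length(cross)) s$timeMin[cross[1]] else NA_real_)
  })
  do.call(rbind, res)
}

#' Phase-integrated plasticity percentage per layer
#'
#' Mean over all post-tetanic samples falling in the immediate, intermediate
#' and long-term windows of (normalized slope - 100), per layer.
#'
#' @param tc a `PotentiationTimecourse`.
#' @param windows named list of `c(start, end)` minutes; a window with no
#'   samples is skipped and flagged in the `missingWindows` attribute.
#' @return data frame: `layer`, `plasticityPct`, `n` (electrodes).
#' @export
plasticityPercent <- function(tc,
    windows = list(immediate = c(0, 5), intermediate = c(5, 60),
                   long = c(60, 120))) {
  tP <- tc$timeMinPost
  covered <- vapply(windows, function(w) any(tP > w[1] & tP <= w[2]), logical(1))
  if (!any(covered)) stopf("time course covers none of the requested windows")
  inWin <- Reduce(`|`, lapply(windows[covered], function(w)
    tP > w[1] & tP <= w[2]))
  layers <- sort(unique(tc$layer))
  out <- do.call(rbind, lapply(layers, function(l) {
    rows <- tc$layer == l
    data.frame(layer = l,
               plasticityPct = mean(tc$normPost[rows, inWin, drop = FALSE]) - 100,
               n = sum(rows))
  }))
  attr(out, "missingWindows") <- names(windows)[!covered]
  if (any(!covered))
    warning("window(s) without samples: ",
            paste(names(windows)[!covered], collapse = ", "))
  out
}

#' Normalized voltage-variation map
#'
#' Peak-to-peak amplitude of the per-electrode mean evoked waveform (after
#' the blank window), normalized to the array maximum within each phase, so
#' values lie in \[0, 1\]; silent electrodes map to 0.
#'
#' @param baseEpochs,postEpochs blanked, centered [EvokedEpochSet-class]s.
#' @return data frame: `channel`, `baseline`, `post_tetanic`.
#' @export
voltageVariationMap <- function(baseEpochs, postEpochs) {
  one <- function(ep) {
    mw <- meanEvokedWaveform(ep)
    cfg <- ep@provenance$config
    post <- ep@timeMs > cfg$blankMs
    p2p <- apply(mw[, post, drop = FALSE], 1, function(v) max(v) - min(v))
    mx <- max(p2p)
    if (mx <= 0) stopf("all-silent array: variation map undefined")
    p2p / mx
  }
  data.frame(channel = seq_len(dim(baseEpochs@epochs)[1]),
             baseline = one(baseEpochs), post_tetanic = one(postEpochs))
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' `D = sup |ECDF_a - ECDF_b|` with the asymptotic p-value.
#'
#' @param a,b numeric samples (non-empty).
#' @return list with `D`, `p`, `nA`, `nB`.
#' @export
compareGroups <- function(a, b) {
  if (!length(a) || !length(b)) stopf("empty sample")
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value,
       nA = length(a), nB = length(b))
}
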