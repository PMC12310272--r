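#' Simulate a complete evoked-LTP session with ground truth
#'
#' Generates the three recordings of the stimulation protocol (input/output
#' sweep, baseline, post-tetanic follow-up) on a full electrode grid, with
#' layer-structured evoked waveforms, distance-dependent peak latencies
#' organized in three separated temporal bands (initial/central/terminal),
#' layer-specific potentiation, per-cluster latency changes and silent-
#' electrode recruitment, plus additive Gaussian noise. All injected values
#' are returned as ground truth.
#'
#' Key construction rules (all recoverable by the analysis operations):
#' \itemize{
#' \item Baseline peak latency of electrode e is
#'   `baselineLatencyMs + distance(e, stimSite)/speed + gap * (band - 1)`,
#'   where bands are distance terciles of the labelled electrodes and `gap`
#'   separates them so the three temporal clusters are well defined.
#' \item Post-tetanic evoked responses are scaled per layer by a gain curve
#'   that ramps to its peak within `earlyPeakMin` minutes and decays linearly
#'   to `decayTo` of peak at end of follow-up, normalized so the session mean
#'   equals the profile gain exactly.
#' \item Post-tetanic peak latencies of baseline-active electrodes are scaled
#'   by `1 + latencyChangePct/100` of their band; recruited electrodes appear
#'   at the scaled band-mean latency, so per-cluster mean latency changes
#'   equal the injected percentages exactly.
#' \item Per band, the baseline-active count is a multiple of 20 (approx.
#'   `activeFraction` of the band) so every default recruitment fold is an
#'   exact count ratio; the required number of silent labelled electrodes is
#'   activated post-tetanically.
#' }
#'
#' @param network `"CA"` or `"DG"`.
#' @param geometry a [GridGeometry-class].
#' @param layers a [LayerMap-class]; default [makeLayerMap()] for the network.
#' @param templates named list of [waveformTemplate()] per layer present.
#' @param profile a [potentiationProfile()]; defaults to the network preset.
#' @param ioModel an [ioResponseModel()].
#' @param noise a [noiseSpec()].
#' @param protocol a [protocolConfig()].
#' @param stimSite length-2 numeric (x, y) in um; default: centroid of the
#'   SR (CA) or ML (DG) band.
#' @param seed integer; drives electrode selection, noise and jitter.
#' @param phases which recordings to generate (subset of
#'   `c("io_sweep", "baseline", "post_tetanic")`).
#' @param propagationSpeed latency propagation speed, m/s.
#' @param clusterGapMs latency gap between temporal bands, ms.
#' @param activeFraction target fraction of labelled electrodes active at
#'   baseline per band.
#' @param jitterCV per-trial multiplicative amplitude jitter CV (disabled
#'   when `noise$sd == 0`).
#' @param artifactUv stimulus-artifact amplitude (uV) rendered in the first
#'   0.5 ms after each pulse; 0 disables.
#' @param analysisBand band (Hz) to which injected peak latencies are
#'   referenced: truth records the peak of the zero-phase band-limited
#'   waveform, which is what peak detection measures.
#' @return an `LtpSession`: list with elements `io_sweep`, `baseline`,
#'   `post_tetanic` ([GridRecording-class] or NULL), `layers`
#'   ([LayerMap-class]), and `truth` (`GroundTruth` list; see Details).
#' @export
simulateSession <- function(network = c("CA", "DG"), geometry = gridGeometry(),
                            layers = NULL, templates = NULL, profile = NULL,
                            ioModel = ioResponseModel(), noise = noiseSpec(),
                            protocol = protocolConfig(), stimSite = NULL,
                            seed = 1L,
                            phases = c("io_sweep", "baseline", "post_tetanic"),
                            propagationSpeed = 0.3, clusterGapMs = 6,
                            activeFraction = 0.4, jitterCV = 0.05,
                            artifactUv = 0, analysisBand = c(1, 500)) {
  network <- match.arg(network)
  phases <- match.arg(phases, several.ok = TRUE)
  layers <- layers %||% makeLayerMap(network, geometry)
  templates <- templates %||% defaultTemplates(network)
  profile <- profile %||% (if (network == "CA") caProfile() else dgProfile())
  labels <- as.character(layerLabels(layers))
  present <- setdiff(unique(labels), "none")
  missing <- setdiff(present, names(templates))
  if (length(missing))
    stopf("no template for layer(s): %s", paste(missing, collapse = ", "))
  missing <- setdiff(present, names(profile$gains))
  if (length(missing))
    stopf("profile has no gain for layer(s): %s", paste(missing, collapse = ", "))

  pos <- electrodePositions(geometry)
  labIdx <- which(labels != "none")
  if (is.null(stimSite)) {
    ref <- if (network == "CA") "SR" else "ML"
    sel <- which(labels == ref)
    if (!length(sel)) sel <- labIdx
    stimSite <- c(mean(pos$x[sel]), mean(pos$y[sel]))
  }
  xmax <- (geometry@nCols - 1) * geometry@pitch
  ymax <- (geometry@nRows - 1) * geometry@pitch
  if (stimSite[1] < 0 || stimSite[1] > xmax || stimSite[2] < 0 || stimSite[2] > ymax)
    stopf("stimSite (%g, %g) um outside the grid extent", stimSite[1], stimSite[2])

  dist <- sqrt((pos$x - stimSite[1])^2 + (pos$y - stimSite[2])^2)

  # temporal bands: distance terciles of labelled electrodes
  nl <- length(labIdx)
  band <- integer(nChannels(geometry))
  ord <- rank(dist[labIdx], ties.method = "first")
  band[labIdx] <- ceiling(3 * ord / nl)
  clusterNames <- c("initial", "central", "terminal")

  # baseline-active / recruited selection per band
  activeBase <- logical(nChannels(geometry))
  recruited <- logical(nChannels(geometry))
  withLocalSeed(seed, {
    for (b in 1:3) {
      bIdx <- labIdx[band[labIdx] == b]
      nBase <- 20L * floor(activeFraction * length(bIdx) / 20)
      if (nBase < 20L)
        stopf("band %d too small (%d electrodes) for activeFraction %g",
              b, length(bIdx), activeFraction)
      baseSel <- sample(bIdx, nBase)
      activeBase[baseSel] <- TRUE
      fold <- profile$recruitmentFold[b]
      nRec <- round(nBase * (fold - 1))
      silent <- setdiff(bIdx, baseSel)
      if (nRec > length(silent))
        stopf("recruitment fold %g unreachable in %s band: need %d silent electrodes, have %d",
              fold, clusterNames[b], nRec, length(silent))
      if (nRec > 0) recruited[sample(silent, nRec)] <- TRUE
    }
  })
  activePost <- activeBase | recruited

  rate <- 14000
  segS <- round(protocol$segmentMs / 1000 * rate)
  marginS <- round(0.150 * rate)    # silent lead/tail; keeps filter edge
                                    # transients away from the epochs
  offMs <- 15                       # pulse onset within each recorded segment
  offS <- round(offMs / 1000 * rate)
  dtMs <- 1000 / rate

  # per-layer template evaluators; peak offsets are referenced to the
  # band-limited waveform the analysis sees (zero-phase 1-500 Hz), so the
  # injected peak latencies are what peak detection recovers
  tplFun <- lapply(templates, makeTemplateFun)
  sosRef <- butterworthSos(4, analysisBand[1], analysisBand[2], rate)
  tPeak <- vapply(names(templates), function(nm) {
    tt <- seq(0, 2 * protocol$segmentMs, by = dtMs)
    w <- tplFun[[nm]](tt)
    if (all(w == 0)) return(attr(tplFun[[nm]], "peakMs"))
    wf <- .cpp_sosfiltfilt_rows(matrix(w, 1), sosRef,
                                as.integer(min(length(w) - 1, 3500)))
    tt[which.max(abs(wf[1, ]))]
  }, numeric(1))
  baseLat <- vapply(templates, function(t) t$baselineLatencyMs, numeric(1))

  # baseline peak latency (ms) for every labelled electrode
  peakBase <- rep(NA_real_, nChannels(geometry))
  peakBase[labIdx] <- baseLat[labels[labIdx]] +
    dist[labIdx] / (1000 * propagationSpeed) + clusterGapMs * (band[labIdx] - 1)

  # post-tetanic peak latency; the baseline-to-post shift is quantized to
  # the sample grid so baseline and post waveforms of an electrode are
  # sampled at the same sub-sample phase (slope ratios stay exact)
  peakPost <- rep(NA_real_, nChannels(geometry))
  bandMeanBase <- vapply(1:3, function(b)
    mean(peakBase[activeBase & band == b]), numeric(1))
  lc <- 1 + profile$latencyChangePct / 100
  sel <- which(activeBase)
  peakPost[sel] <- peakBase[sel] +
    round(peakBase[sel] * (lc[band[sel]] - 1) / dtMs) * dtMs
  sel <- which(recruited)
  peakPost[sel] <- round(bandMeanBase[band[sel]] * lc[band[sel]] / dtMs) * dtMs

  # gain curve over the recorded post schedule, normalized to session mean
  sched <- protocol$postScheduleMin
  gainShape <- gainTimeShape(sched, profile)
  gainAt <- function(layer) profile$gains[[layer]] * gainShape

  # calibration intensity implied by the I/O model
  intensities <- seq(protocol$ioStart, protocol$ioStop, by = protocol$ioStep)
  u <- ioScale(ioModel, intensities)
  target <- protocol$calibFraction * max(u)
  iSel <- intensities[which.min(abs(u - target))]

  # evaluation grid for the evoked waveform, spanning two segments so
  # template tails continue across segment boundaries
  tRel <- ((seq_len(2L * segS) - 1) - offS) / rate * 1000

  noiseSeed <- as.double(noise$seed %||% seed)
  useJitter <- noise$sd > 0 && jitterCV > 0

  buildPhase <- function(phase, nominalMin, intensity, scaleFun, latVec,
                         activeVec, seedOffN, seedOffJ) {
    nPulse <- length(nominalMin)
    nchan <- nChannels(geometry)
    total <- segS * nPulse + 2L * marginS
    vol <- .cpp_noise_mat(nchan, total, noise$sd, noiseSeed * 8 + seedOffN)
    act <- which(activeVec)
    scale <- scaleFun(act)           # |act| x nPulse matrix of amplitude factors
    if (useJitter)
      scale <- scale * (1 + jitterCV *
        matrix(gaussNoise(length(act) * nPulse, noiseSeed * 8 + seedOffJ),
               length(act), nPulse))
    tSeg <- tRel[seq_len(segS)]
    art <- if (artifactUv != 0)
      artifactUv * exp(-pmax(tSeg, 0) / 0.3) * (tSeg >= 0 & tSeg <= 1.5) else NULL
    W <- matrix(0, length(act), 2L * segS)
    for (j in seq_along(act)) {
      e <- act[j]
      lay <- labels[e]
      W[j, ] <- tplFun[[lay]](tRel - (latVec[e] - tPeak[[lay]]))
    }
    .cpp_add_evoked(vol, as.integer(act - 1L), W, scale, as.integer(segS),
                    as.integer(marginS))
    if (!is.null(art))
      for (k in seq_len(nPulse)) {
        cols <- marginS + ((k - 1) * segS + 1):(k * segS)
        vol[, cols] <- sweep(vol[, cols, drop = FALSE], 2, art, "+")
      }
    ev <- data.frame(time = marginS / rate + (seq_len(nPulse) - 1) * segS / rate +
                       offMs / 1000,
                     intensity = intensity,
                     half_width_us = protocol$halfWidthUs,
                     site_x = stimSite[1], site_y = stimSite[2],
                     kind = "test_pulse", nominal_min = nominalMin)
    gridRecording(vol, rate = rate, geometry = geometry, events = ev,
                  phase = phase, t0 = 0)
  }

  out <- list(io_sweep = NULL, baseline = NULL, post_tetanic = NULL)
  uSel <- ioScale(ioModel, iSel)
  if ("io_sweep" %in% phases) {
    sc <- ioScale(ioModel, intensities) / uSel
    out$io_sweep <- buildPhase("io_sweep", rep(NA_real_, length(intensities)),
      intensities,
      function(act) matrix(sc, length(act), length(intensities), byrow = TRUE),
      peakBase, activeBase, 1, 5)
  }
  if ("baseline" %in% phases) {
    nb <- protocol$baselinePulses
    # recorded pulses are a thinned subset of a 10 min stable baseline
    nomB <- -rev(seq_len(nb)) * 10 / nb
    out$baseline <- buildPhase("baseline", nomB, iSel,
      function(act) matrix(1, length(act), nb),
      peakBase, activeBase, 2, 6)
  }
  if ("post_tetanic" %in% phases) {
    out$post_tetanic <- buildPhase("post_tetanic", sched, iSel,
      function(act) {
        g <- vapply(labels[act], function(l) profile$gains[[l]], numeric(1))
        1 + outer(g, gainShape) / 100
      },
      peakPost, activePost, 3, 7)
  }

  clusters <- data.frame(
    cluster = clusterNames,
    nBase = vapply(1:3, function(b) sum(activeBase & band == b), integer(1)),
    nPost = vapply(1:3, function(b) sum(activePost & band == b), integer(1)),
    fold = profile$recruitmentFold,
    latencyChangePct = profile$latencyChangePct,
    meanLatencyBaseMs = bandMeanBase,
    meanLatencyPostMs = vapply(1:3, function(b)
      mean(peakPost[activePost & band == b]), numeric(1)))

  electrodes <- data.frame(
    pos,
    layer = labels,
    distanceUm = dist,
    band = factor(ifelse(band == 0, NA, clusterNames[pmax(band, 1)]),
                  levels = clusterNames),
    activeBase = activeBase, activePost = activePost, recruited = recruited,
    peakLatencyBaseMs = peakBase, peakLatencyPostMs = peakPost,
    gainPct = ifelse(labels %in% names(profile$gains),
                     unlist(profile$gains)[labels], NA_real_))

  truth <- structure(list(
    electrodes = electrodes, clusters = clusters,
    profile = profile, network = network, stimSite = stimSite,
    selectedIntensity = iSel, noiseSd = noise$sd, seed = seed,
    propagationSpeed = propagationSpeed, clusterGapMs = clusterGapMs,
    gainShapeMean = mean(gainTimeShape(sched, profile))),
    class = c("GroundTruth", "list"))

  structure(list(io_sweep = out$io_sweep, baseline = out$baseline,
                 post_tetanic = out$post_tetanic, layers = layers,
                 truth = truth, protocol = protocol, network = network),
            class = c("LtpSession", "list"))
}

#' Gain time course shape, normalized to unit session mean
#'
#' Piecewise-linear ramp to 1 at `earlyPeakMin`, then linear decay to
#' `decayTo` at the last scheduled time, rescaled so the mean over the
#' recorded post-tetanic schedule is exactly 1 (so the session-mean gain
#' equals the nominal profile gain).
#' @noRd
gainTimeShape <- function(scheduleMin, profile) {
  if (profile$gainShape == "constant") return(rep(1, length(scheduleMin)))
  pk <- profile$earlyPeakMin
  Tend <- max(max(scheduleMin), pk + 1e-9)
  r <- ifelse(scheduleMin <= pk, scheduleMin / pk,
              1 - (1 - profile$decayTo) * (scheduleMin - pk) / (Tend - pk))
  r / mean(r)
}
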