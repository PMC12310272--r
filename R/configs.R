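#' Stimulation-recording protocol configuration
#'
#' Encodes the calibration and LTP-induction protocol: an input/output sweep
#' in 10 uA steps from 20 to 130 uA at 30 s intervals, test pulses at
#' 0.033 Hz at the intensity evoking `calibFraction` (60%) of the maximum
#' fEPSP slope, a single 100 Hz / 1 s high-frequency train (10 ms inter-pulse
#' interval), and a follow-up of `followUpMin` minutes. LTP is called when
#' post-HFS responses exceed baseline by at least `ltpThresholdPct` percent.
#'
#' `baselinePulses` and `postScheduleMin` set which test pulses of the
#' nominal 0.033 Hz schedule are actually recorded (a thinned subset keeps
#' synthetic sessions tractable; each recorded pulse carries its nominal
#' protocol time in minutes relative to HFS).
#'
#' @param ioStart,ioStop,ioStep I/O sweep intensities, uA.
#' @param ioIntervalS I/O inter-pulse interval, s.
#' @param testRateHz test-pulse rate, Hz.
#' @param hfsFreq,hfsInterPulseMs,hfsDurationS HFS train parameters.
#' @param calibFraction fraction of maximum fEPSP slope targeted by
#'   calibration (0 < f < 1).
#' @param ltpThresholdPct LTP criterion, percent above baseline.
#' @param followUpMin post-tetanic follow-up duration, minutes.
#' @param halfWidthUs stimulus pulse half-width, us (admissible 70-140).
#' @param baselinePulses number of recorded baseline test pulses.
#' @param postScheduleMin nominal times (min after HFS) of recorded
#'   post-tetanic test pulses.
#' @param segmentMs recorded segment length per test pulse, ms.
#' @return a `ProtocolConfig` (validated list).
#' @export
protocolConfig <- function(ioStart = 20, ioStop = 130, ioStep = 10,
                           ioIntervalS = 30, testRateHz = 0.033,
                           hfsFreq = 100, hfsInterPulseMs = 10, hfsDurationS = 1,
                           calibFraction = 0.60, ltpThresholdPct = 40,
                           followUpMin = 120, halfWidthUs = 100,
                           baselinePulses = 10,
                           postScheduleMin = c(1, 2, 3, 4, 5, 10, 20, 30, 40,
                                               50, 60, 75, 90, 105, 120),
                           segmentMs = 120) {
  if (ioStart >= ioStop) stopf("ioStart must be < ioStop")
  assertScalarNum(calibFraction, "calibFraction", 1e-9, 1 - 1e-9)
  assertScalarNum(ltpThresholdPct, "ltpThresholdPct", 1e-9, Inf)
  assertScalarNum(halfWidthUs, "halfWidthUs", 70, 140)
  if (any(diff(postScheduleMin) <= 0)) stopf("postScheduleMin must be increasing")
  if (max(postScheduleMin) > followUpMin)
    stopf("postScheduleMin exceeds followUpMin")
  structure(list(ioStart = ioStart, ioStop = ioStop, ioStep = ioStep,
                 ioIntervalS = ioIntervalS, testRateHz = testRateHz,
                 hfsFreq = hfsFreq, hfsInterPulseMs = hfsInterPulseMs,
                 hfsDurationS = hfsDurationS, calibFraction = calibFraction,
                 ltpThresholdPct = ltpThresholdPct, followUpMin = followUpMin,
                 halfWidthUs = halfWidthUs, baselinePulses = baselinePulses,
                 postScheduleMin = postScheduleMin, segmentMs = segmentMs),
            class = c("ProtocolConfig", "list"))
}

#' Preprocessing configuration
#'
#' Fourth-order Butterworth band-pass (1-500 Hz), applied zero-phase;
#' stimulus artifact blanking by linear interpolation over `(0, blankMs]`;
#' epochs cut from `-epochPreMs` to `+epochPostMs` around each test pulse
#' with per-epoch pre-stimulus baseline subtraction.
#'
#' @param bandLow,bandHigh band edges, Hz.
#' @param order Butterworth order.
#' @param blankMs post-stimulus blanking window, ms.
#' @param epochPreMs,epochPostMs epoch extent around stimulus onset, ms.
#' @return a `PreprocessConfig` (validated list).
#' @export
preprocessConfig <- function(bandLow = 1, bandHigh = 500, order = 4,
                             blankMs = 2, epochPreMs = 10, epochPostMs = 100) {
  if (!(0 < bandLow && bandLow < bandHigh)) stopf("need 0 < bandLow < bandHigh")
  if (blankMs >= epochPostMs) stopf("blank window must end before the epoch does")
  structure(list(bandLow = bandLow, bandHigh = bandHigh, order = order,
                 blankMs = blankMs, epochPreMs = epochPreMs,
                 epochPostMs = epochPostMs),
            class = c("PreprocessConfig", "list"))
}

#' Additive recording-noise specification
#'
#' Gaussian, i.i.d. per sample. `sd = 0` gives noise-free sessions (the
#' generator then also disables per-trial amplitude jitter).
#'
#' @param sd noise standard deviation, uV.
#' @param seed optional integer; when `NULL` the session seed is used.
#' @export
noiseSpec <- function(sd = 10, seed = NULL) {
  assertScalarNum(sd, "sd", 0, Inf)
  structure(list(sd = sd, seed = seed), class = c("NoiseSpec", "list"))
}

#' Sigmoidal stimulus-intensity / fEPSP-slope response model
#'
#' Logistic input/output relation used by the generator: the evoked response
#' at intensity I is scaled by `u(I) = 1 / (1 + exp(-(I - halfUa)/steepUa))`,
#' normalized to the calibration intensity. Strictly increasing in I.
#'
#' @param maxSlope notional maximum fEPSP slope, uV/ms (scales reports only).
#' @param halfUa half-activation intensity, uA.
#' @param steepUa steepness, uA.
#' @export
ioResponseModel <- function(maxSlope = 60, halfUa = 70, steepUa = 18) {
  assertScalarNum(steepUa, "steepUa", 1e-9, Inf)
  structure(list(maxSlope = maxSlope, halfUa = halfUa, steepUa = steepUa),
            class = c("IOResponseModel", "list"))
}

ioScale <- function(model, intensity) {
  1 / (1 + exp(-(intensity - model$halfUa) / model$steepUa))
}

#' Evoked waveform template
#'
#' Parametric template of the evoked extracellular response at one electrode:
#' `EPSP` is a negative-going difference of exponentials
#' `a * (exp(-t/decayTau) - exp(-t/riseTau))`; `PS` superposes a narrow
#' biphasic population-spike transient (width `psWidthMs`) on the EPSP rising
#' phase; `multiphasic` adds a delayed opposite-sign lobe to the EPSP. All
#' templates are rescaled so the global extremum equals `amplitude` and are
#' zero at onset.
#'
#' @param kind `"EPSP"`, `"PS"` or `"multiphasic"`.
#' @param amplitude signed extremum, uV (EPSPs negative-going).
#' @param riseTau,decayTau time constants, ms (`riseTau < decayTau`).
#' @param psWidthMs population-spike width, ms (PS kind only).
#' @param psGain PS lobe size relative to the EPSP extremum (PS kind only).
#' @param baselineLatencyMs peak latency at the stimulation site, ms.
#' @export
waveformTemplate <- function(kind = c("EPSP", "PS", "multiphasic"),
                             amplitude = -120, riseTau = 2, decayTau = 12,
                             psWidthMs = 2, psGain = 1.5,
                             baselineLatencyMs = 12) {
  kind <- match.arg(kind)
  if (riseTau >= decayTau) stopf("riseTau must be < decayTau")
  if (amplitude == 0) warning("zero-amplitude template renders a silent electrode")
  structure(list(kind = kind, amplitude = amplitude, riseTau = riseTau,
                 decayTau = decayTau, psWidthMs = psWidthMs, psGain = psGain,
                 baselineLatencyMs = baselineLatencyMs),
            class = c("WaveformTemplate", "list"))
}

#' Default per-layer waveform templates
#'
#' Waveform-to-layer attribution follows the physiology of the slice: SP and
#' GCL carry population spikes from synchronized somatic firing, SR/SLM/ML
#' carry dendritic EPSPs (SLM slower and smaller, reflecting distal inputs),
#' SO is multiphasic, and the hilus mixes EPSP and PS components. Absolute
#' amplitudes and time constants are generator defaults, not measured values.
#'
#' @param network `"CA"` or `"DG"`.
#' @return named list of [waveformTemplate()]s, one per layer.
#' @export
defaultTemplates <- function(network = c("CA", "DG")) {
  network <- match.arg(network)
  if (network == "CA") {
    list(SO = waveformTemplate("multiphasic", amplitude = -150, riseTau = 2, decayTau = 12),
         SP = waveformTemplate("PS", amplitude = -300, riseTau = 2, decayTau = 12,
                               psWidthMs = 2, psGain = 1.5),
         SR = waveformTemplate("EPSP", amplitude = -120, riseTau = 2, decayTau = 12),
         SLM = waveformTemplate("EPSP", amplitude = -80, riseTau = 4, decayTau = 25))
  } else {
    list(ML = waveformTemplate("EPSP", amplitude = -100, riseTau = 3, decayTau = 18),
         GCL = waveformTemplate("PS", amplitude = -250, riseTau = 2, decayTau = 12,
                                psWidthMs = 2, psGain = 1.5),
         H = waveformTemplate("PS", amplitude = -150, riseTau = 3, decayTau = 20,
                              psWidthMs = 3, psGain = 0.8))
  }
}

#' Layer-specific potentiation profile
#'
#' Describes the injected post-tetanic effect: sustained per-layer gain in
#' percent of baseline (session-mean of the potentiation time course), the
#' per-temporal-cluster percent change in peak latency (negative = faster),
#' and the per-temporal-cluster fold increase in active-electrode counts.
#' The gain time course is a biphasic ramp peaking at `earlyPeakMin` minutes
#' and decaying linearly to `decayTo` of the peak at the end of follow-up,
#' normalized so its session mean equals the nominal gain
#' (`gainShape = "constant"` holds the gain flat instead).
#'
#' @param gains named numeric, percent per layer.
#' @param latencyChangePct length-3 numeric, percent change for the
#'   initial/central/terminal clusters.
#' @param recruitmentFold length-3 numeric, fold increase in active counts
#'   for the initial/central/terminal clusters.
#' @param earlyPeakMin time of peak potentiation, minutes.
#' @param decayTo fraction of peak gain retained at end of follow-up.
#' @param gainShape `"biphasic"` or `"constant"`.
#' @export
potentiationProfile <- function(gains, latencyChangePct, recruitmentFold,
                                earlyPeakMin = 5, decayTo = 0.6,
                                gainShape = c("biphasic", "constant")) {
  gainShape <- match.arg(gainShape)
  stopifnot(length(latencyChangePct) == 3L, length(recruitmentFold) == 3L,
            all(is.finite(unlist(gains))), all(recruitmentFold >= 1))
  names(latencyChangePct) <- names(recruitmentFold) <-
    c("initial", "central", "terminal")
  structure(list(gains = unlist(gains), latencyChangePct = latencyChangePct,
                 recruitmentFold = recruitmentFold, earlyPeakMin = earlyPeakMin,
                 decayTo = decayTo, gainShape = gainShape),
            class = c("PotentiationProfile", "list"))
}

#' Named potentiation profiles
#'
#' `caProfile()` and `dgProfile()` carry the default young-adult effect sizes
#' for the CA1-CA3 and DG networks; `agedProfile()` and `youngProfile()` are
#' the CA aging-contrast presets. For the aging presets, SP and SR gains are
#' the contrast-defining values; SO and SLM inherit the CA defaults scaled by
#' the corresponding SP ratio (a modeling choice for the layers the contrast
#' does not pin down).
#'
#' @return a [potentiationProfile()].
#' @export
caProfile <- function() {
  potentiationProfile(gains = c(SO = 82, SP = 47, SR = 31, SLM = 54),
                      latencyChangePct = c(-6, -4.8, -13.8),
                      recruitmentFold = c(1.5, 1.8, 2.25))
}

#' @rdname caProfile
#' @export
dgProfile <- function() {
  potentiationProfile(gains = c(ML = 35, GCL = 157, H = 122),
                      latencyChangePct = c(-7.3, -4.8, 10.8),
                      recruitmentFold = c(1.8, 1.7, 1.9))
}

#' @rdname caProfile
#' @export
agedProfile <- function() {
  r <- 38 / 47
  potentiationProfile(gains = c(SO = 82 * r, SP = 38, SR = 21, SLM = 54 * r),
                      latencyChangePct = c(-6, -4.8, -13.8),
                      recruitmentFold = c(1.5, 1.8, 2.25))
}

#' @rdname caProfile
#' @export
youngProfile <- function() {
  r <- 49.9 / 47
  potentiationProfile(gains = c(SO = 82 * r, SP = 49.9, SR = 24.8, SLM = 54 * r),
                      latencyChangePct = c(-6, -4.8, -13.8),
                      recruitmentFold = c(1.5, 1.8, 2.25))
}

#' Homogeneous forward model for CSD estimation
#'
#' Extracellular conductivity `sigma` (S/m) and slice thickness `h` (um);
#' sources are treated as uniform across the slice thickness in a
#' homogeneous medium, giving the thickness-integrated inverse-distance
#' weight `w(d; h) = integral dz / sqrt(d^2 + z^2)` over `z` in `[-h/2, h/2]`.
#'
#' @param sigma conductivity, S/m.
#' @param thicknessUm slice thickness, um.
#' @export
forwardModel <- function(sigma = 0.3, thicknessUm = 300) {
  assertScalarNum(sigma, "sigma", 1e-12, Inf)
  assertScalarNum(thicknessUm, "thicknessUm", 1e-12, Inf)
  structure(list(sigma = sigma, thicknessUm = thicknessUm),
            class = c("ForwardModel", "list"))
}

#' kCSD estimation configuration
#'
#' Gaussian basis sources on an `basisM` x `basisM` grid spanning the
#' electrode extent, basis width `basisWidthUm` (default twice the electrode
#' pitch), estimation grid matching the electrode grid, ridge parameter
#' `lambda`, and a candidate grid for leave-one-electrode-out selection.
#'
#' @param basisM basis grid extent per side.
#' @param basisWidthUm Gaussian basis width R, um.
#' @param lambda ridge regularization (>= 0).
#' @param lambdaCandidates candidates for [selectLambda()].
#' @export
kcsdConfig <- function(basisM = 32, basisWidthUm = 84, lambda = 1e-6,
                       lambdaCandidates = 10^seq(-8, 0, by = 1)) {
  assertScalarNum(basisWidthUm, "basisWidthUm", 1e-9, Inf)
  assertScalarNum(lambda, "lambda", 0, Inf)
  structure(list(basisM = as.integer(basisM), basisWidthUm = basisWidthUm,
                 lambda = lambda, lambdaCandidates = lambdaCandidates),
            class = c("KCSDConfig", "list"))
}
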