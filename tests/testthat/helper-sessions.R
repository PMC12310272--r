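# Shared session fixtures, generated in code and cached for the test run.

.sessionCache <- new.env(parent = emptyenv())

# Compact analysis of a full-scale session, cached by configuration.
cachedAnalysis <- function(network, seed, profile = NULL, noiseSd = 10,
                           label = "default") {
  key <- paste(network, label, noiseSd, seed, sep = "|")
  if (!is.null(.sessionCache[[key]])) return(.sessionCache[[key]])
  t0 <- Sys.time()
  res <- analyzeSession(
    simulateSession(network, profile = profile, noise = noiseSpec(noiseSd),
                    seed = seed, phases = c("baseline", "post_tetanic")),
    classifySeed = seed)
  res$elapsedSec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  .sessionCache[[key]] <- res
  res
}

# Small-grid session parameters used by the unit tests.
smallGeometry <- function() gridGeometry(16, 16)

smallLayers <- function(network = "CA") {
  spec <- if (network == "CA") bandSpec(c(SO = 3, SP = 2, SR = 4, SLM = 3))
          else bandSpec(c(ML = 5, GCL = 3, H = 4))
  makeLayerMap(network, smallGeometry(), spec)
}

smallSession <- function(network = "CA", seed = 1, noiseSd = 0,
                         profile = NULL, phases = c("baseline", "post_tetanic"),
                         ...) {
  simulateSession(network, geometry = smallGeometry(),
                  layers = smallLayers(network), profile = profile,
                  noise = noiseSpec(noiseSd), seed = seed, phases = phases,
                  ...)
}

# Uniform profile helper (same gain everywhere, no latency/recruitment
# effects) for controlled LTP-detection tests.
uniformProfile <- function(gain, network = "CA", shape = "constant") {
  layers <- if (network == "CA") c("SO", "SP", "SR", "SLM")
            else c("ML", "GCL", "H")
  potentiationProfile(gains = stats::setNames(rep(gain, length(layers)), layers),
                      latencyChangePct = c(0, 0, 0),
                      recruitmentFold = c(1, 1, 1), gainShape = shape)
}

# Minimal synthetic EvokedEpochSet built directly from a waveform matrix
# (one epoch per electrode), for unit tests of feature/variation code.
epochsFromWaveforms <- function(waves, rate = 14000, preMs = 10, nEpochs = 1,
                                cfg = preprocessConfig()) {
  nel <- nrow(waves)
  len <- ncol(waves)
  preS <- round(preMs / 1000 * rate)
  arr <- array(0, dim = c(nel, nEpochs, len))
  for (k in seq_len(nEpochs)) arr[, k, ] <- waves
  new("EvokedEpochSet", epochs = arr,
      timeMs = (seq_len(len) - 1 - preS) / rate * 1000,
      rate = rate,
      events = do.call(rbind, rep(list(netLTP:::completeEvents(
        data.frame(time = 0.1))), nEpochs)),
      phase = "baseline",
      provenance = list(config = cfg, geometry = NULL,
                        blanked = TRUE, centered = TRUE))
}
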