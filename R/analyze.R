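#' Analyze a simulated or loaded session end to end
#'
#' Runs preprocessing, waveform classification, temporal clustering and LTP
#' quantification on one session and returns a compact result list (no
#' large arrays), releasing the voltage matrices as soon as they are
#' epoched. Pass the session expression directly
#' (`analyzeSession(simulateSession(...))`) to keep peak memory low.
#'
#' @param session an `LtpSession` (from [simulateSession()] or
#'   [loadSession()]) with `baseline` and `post_tetanic` recordings.
#' @param preprocess a [preprocessConfig()].
#' @param activityThresholdSd activity threshold for all detection steps.
#' @param classifySeed seed for the k-means restarts.
#' @param doClassify set `FALSE` to skip classification.
#' @return list with `network`, `truth`, classification accuracies and
#'   confusions per phase, `latency` (cluster assignments, percent change,
#'   recruitment folds), `plasticity` (per layer), `electrodePlasticity`
#'   (per electrode), `detect` (LTP flags/onsets), `activeBase`/`activePost`
#'   counts.
#' @export
analyzeSession <- function(session, preprocess = preprocessConfig(),
                           activityThresholdSd = 6, classifySeed = 1L,
                           doClassify = TRUE) {
  stopifnot(inherits(session, "LtpSession"))
  layers <- session$layers
  protocol <- session$protocol %||% protocolConfig()
  epB <- preprocessRecording(session$baseline, preprocess)
  session$baseline <- NULL
  epP <- preprocessRecording(session$post_tetanic, preprocess)
  session$post_tetanic <- NULL
  gc(FALSE)
  ftB <- extractFeatures(epB, activityThresholdSd)
  ftP <- extractFeatures(epP, activityThresholdSd)
  out <- list(network = session$network, truth = session$truth)
  if (doClassify) {
    k <- if (session$network == "CA") 4L else 3L
    scB <- scoreClassification(classifyWaveforms(ftB, k, seed = classifySeed),
                               layers)
    scP <- scoreClassification(classifyWaveforms(ftP, k, seed = classifySeed),
                               layers)
    out$accuracyBaseline <- scB$accuracy
    out$accuracyPost <- scP$accuracy
    out$confusionBaseline <- scB$confusion
  }
  tabB <- peakLatency(epB, activityThresholdSd, features = ftB)
  tabP <- peakLatency(epP, activityThresholdSd, features = ftP)
  clB <- clusterLatencies(tabB)
  clP <- clusterLatencies(tabP)
  out$latency <- list(baseline = clB, post = clP,
                      changePct = latencyChange(clB, clP),
                      recruitmentFold = recruitment(clB, clP),
                      tables = list(baseline = tabB, post = tabP))
  out$activeBase <- sum(tabB$active)
  out$activePost <- sum(tabP$active)
  tc <- potentiationTimecourse(epB, epP, layers, activityThresholdSd,
                               features = ftB)
  out$plasticity <- plasticityPercent(tc)
  out$detect <- detectLtp(tc, protocol)
  win <- tc$timeMinPost > 0 & tc$timeMinPost <= 120
  out$electrodePlasticity <- data.frame(
    channel = tc$channel, layer = tc$layer,
    pct = rowMeans(tc$normPost[, win, drop = FALSE]) - 100)
  out
}
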