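test_that("scalar features follow their definitions", {
  rate <- 14000
  n <- 1541
  tm <- (seq_len(n) - 1 - 140) / rate * 1000
  # waveform with min -120 and max +30 -> peak-to-peak 150
  w1 <- numeric(n)
  w1[tm > 5 & tm < 8] <- -120
  w1[tm > 20 & tm < 23] <- 30
  # linear ramp at -10 uV/ms from 3 ms to peak
  w2 <- numeric(n)
  ramp <- tm > 3 & tm <= 15
  w2[ramp] <- -10 * (tm[ramp] - 3)
  w2[tm > 15] <- -120
  ep <- epochsFromWaveforms(rbind(w1, w2, 0), nEpochs = 3)
  ft <- extractFeatures(ep, activityThresholdSd = 6)$features
  expect_equal(ft$p2pUv[1], 150)
  expect_equal(ft$slopeUvMs[2], 10, tolerance = 0.02 * 10)
  # all-zero electrode: features zero and inactive
  expect_false(ft$active[3])
  expect_identical(ft$p2pUv[3], 0)
  expect_identical(ft$slopeUvMs[3], 0)
})

test_that("k-means recovers well-separated clouds and rejects degenerate input", {
  set.seed(1)
  n <- 40
  waves <- rbind(matrix(rnorm(n / 2 * 30, 0, 0.1), n / 2),
                 matrix(rnorm(n / 2 * 30, 8, 0.1), n / 2))
  ft <- structure(list(
    features = data.frame(channel = 1:n, p2pUv = abs(waves[, 1]) + 10,
                          slopeUvMs = 1, latencyMs = 5,
                          amplitudeUv = waves[, 1], active = TRUE),
    waveforms = waves, phase = "baseline", activityThresholdSd = 6),
    class = c("WaveformFeatureTable", "list"))
  res <- classifyWaveforms(ft, 2, seed = 3)
  truth <- rep(1:2, each = n / 2)
  expect_true(length(unique(res$cluster[truth == 1])) == 1 &&
              length(unique(res$cluster[truth == 2])) == 1 &&
              res$cluster[1] != res$cluster[n])
  # deterministic given seed
  res2 <- classifyWaveforms(ft, 2, seed = 3)
  expect_identical(res$cluster, res2$cluster)
  # identical rows: diagnostic error
  ftSame <- ft
  ftSame$waveforms[] <- 1
  ftSame$features$p2pUv <- 1
  expect_error(classifyWaveforms(ftSame, 2, seed = 1), "degenerate")
  # too few active electrodes
  ftFew <- ft
  ftFew$features$active <- c(TRUE, rep(FALSE, n - 1))
  expect_error(classifyWaveforms(ftFew, 2, seed = 1), "active electrodes")
})

test_that("confusion scoring implements the mean diagonal probability", {
  mkRes <- function(cluster, channel)
    structure(list(channel = channel, cluster = cluster, k = 2L),
              class = c("ClassificationResult", "list"))
  lm <- layerMap(c(rep("SO", 10), rep("SP", 10)), "CA")
  # perfect assignment -> accuracy 1 (regardless of label permutation)
  perfect <- mkRes(rep(c(2L, 1L), each = 10), 1:20)
  expect_equal(scoreClassification(perfect, lm)$accuracy, 1)
  # confusion [[8,2],[1,9]] -> (0.8 + 0.9) / 2
  cl <- c(rep(1L, 8), rep(2L, 2), rep(1L, 1), rep(2L, 9))
  sc <- scoreClassification(mkRes(cl, 1:20), lm)
  expect_equal(sc$accuracy, 0.85)
  expect_equal(rowSums(sc$confusion), c(SO = 1, SP = 1))
  # permutation invariance: relabeling clusters never changes accuracy
  sc2 <- scoreClassification(mkRes(3L - cl, 1:20), lm)
  expect_equal(sc2$accuracy, sc$accuracy)
})

test_that("random labels on balanced classes score near chance", {
  set.seed(7)
  n <- 4000
  lm <- layerMap(rep(c("SO", "SP", "SR", "SLM"), each = n / 4), "CA")
  res <- structure(list(channel = 1:n, cluster = sample(1:4, n, TRUE), k = 4L),
                   class = c("ClassificationResult", "list"))
  acc <- scoreClassification(res, lm)$accuracy
  # Monte-Carlo oracle: 1/k, plus assignment-optimisation inflation O(1/sqrt(n))
  expect_equal(acc, 0.25, tolerance = 0.05)
})

test_that("noise-free small sessions classify exactly into their layers", {
  a <- analyzeSession(smallSession(network = "CA", seed = 8, noiseSd = 0),
                      classifySeed = 8)
  expect_equal(a$accuracyBaseline, 1)
  b <- analyzeSession(smallSession(network = "DG", seed = 8, noiseSd = 0),
                      classifySeed = 8)
  expect_equal(b$accuracyBaseline, 1)
})

test_that("classification accuracy does not improve with added noise", {
  acc <- sapply(c(0, 40, 160), function(sd) {
    mean(sapply(1:3, function(seed) {
      a <- analyzeSession(smallSession(seed = seed, noiseSd = sd),
                          classifySeed = seed)
      a$accuracyBaseline
    }))
  })
  # non-increasing up to sampling error
  expect_true(all(diff(acc) <= 0.05))
  expect_equal(acc[1], 1)
})
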