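test_that("fEPSP slope matches analytic ramps and scales linearly", {
  rate <- 14000
  n <- 1541
  tm <- (seq_len(n) - 1 - 140) / rate * 1000
  ramp <- numeric(n)
  rising <- tm > 3 & tm <= 7                  # to -120 uV over 4 ms
  ramp[rising] <- -30 * (tm[rising] - 3)
  ramp[tm > 7] <- -120
  expect_equal(as.numeric(fepspSlope(ramp, tm)), 30, tolerance = 0.02 * 30)
  expect_equal(as.numeric(fepspSlope(2 * ramp, tm)),
               2 * as.numeric(fepspSlope(ramp, tm)), tolerance = 1e-9)
  flat <- fepspSlope(numeric(n), tm)
  expect_identical(as.numeric(flat), 0)
  expect_true(attr(flat, "flagged"))
})

test_that("per-pulse slopes coincide with the single-epoch fit when noise-free", {
  rate <- 14000
  w <- renderTemplate(waveformTemplate("EPSP", -120, 2, 12), rate, 100)
  n <- 1541
  wave <- numeric(n)
  wave[183:n] <- w[seq_len(n - 182)]
  ep <- epochsFromWaveforms(rbind(wave, 0.5 * wave), nEpochs = 3)
  sl <- epochSlopes(ep)
  single <- as.numeric(fepspSlope(wave, epochTimeMs(ep)))
  expect_equal(unname(sl[1, ]), rep(single, 3), tolerance = 1e-9)
  expect_equal(unname(sl[2, ]), rep(single / 2, 3), tolerance = 1e-9)
})

test_that("calibration selects the intensity nearest 60% of the maximum slope", {
  io <- selectIntensity(seq(20, 80, 10), c(5, 10, 20, 35, 50, 58, 60))
  expect_equal(io$targetSlope, 36)
  expect_equal(io$selectedIntensity, 50)     # slope 35 is nearest to 36
  # strictly linear curve: selection lands near 60% of the range end
  lin <- selectIntensity(seq(20, 130, 10), 1:12)
  expect_equal(lin$selectedIntensity, 80)    # 7.2 -> slope 7 at 80 uA
  expect_error(selectIntensity(1:5, rep(0, 5)), "calibration failure")
  expect_error(selectIntensity(c(1, 1, 2), 1:3), "strictly increasing")
})

test_that("calibrating a simulated I/O sweep recovers the generator's choice", {
  s <- smallSession(seed = 9, noiseSd = 0, phases = "io_sweep")
  io <- calibrate(s$io_sweep)
  expect_equal(io$selectedIntensity, s$truth$selectedIntensity)
  expect_equal(io$intensities, seq(20, 130, 10))
  # slopes strictly increasing along the sweep (sigmoidal response model)
  expect_true(all(diff(io$slopes) > 0))
})

test_that("a null session yields a flat 100% time course", {
  a <- analyzeSession(smallSession(seed = 3, noiseSd = 0,
                                   profile = uniformProfile(0)),
                      doClassify = FALSE)
  # residual is filter crosstalk from neighbouring-pulse tails (~0.01%)
  expect_lt(max(abs(a$plasticity$plasticityPct)), 0.05)
  expect_false(any(a$detect$ltp))
})

test_that("baseline normalization makes the baseline window exactly 100%", {
  s <- smallSession(seed = 4, noiseSd = 5)
  epB <- preprocessRecording(s$baseline)
  epP <- preprocessRecording(s$post_tetanic)
  tc <- potentiationTimecourse(epB, epP, s$layers)
  expect_equal(unname(rowMeans(tc$normBase)),
               rep(100, nrow(tc$normBase)), tolerance = 1e-9)
})

test_that("LTP detection is inclusive at threshold and monotone in gain", {
  # boundary rule on a constructed time course: >= is inclusive
  mkTc <- function(pct) {
    sched <- protocolConfig()$postScheduleMin
    structure(list(aggregate = data.frame(
      phase = "post_tetanic", timeMin = sched, layer = "SR", pct = pct),
      timeMinPost = sched), class = c("PotentiationTimecourse", "list"))
  }
  expect_true(detectLtp(mkTc(140))$ltp)          # exactly +40%: inclusive
  expect_false(detectLtp(mkTc(139.99))$ltp)
  expect_equal(detectLtp(mkTc(140))$onsetMin, 1)
  # monotone in injected gain on noise-free sessions
  flags <- sapply(c(0, 20, 40, 60, 100, 160), function(g) {
    a <- analyzeSession(smallSession(seed = 5, noiseSd = 0,
                                     profile = uniformProfile(g)),
                        doClassify = FALSE)
    all(a$detect$ltp)
  })
  expect_true(all(diff(flags) >= 0))             # never un-flags as gain grows
  expect_identical(flags[c(1, 2, 4, 5, 6)], c(FALSE, FALSE, TRUE, TRUE, TRUE))
  # onset: sustained 50% gain crosses within the first 5 post-HFS pulses
  a50 <- analyzeSession(smallSession(seed = 5, noiseSd = 0,
                                     profile = uniformProfile(50)),
                        doClassify = FALSE)
  sched <- protocolConfig()$postScheduleMin
  expect_true(all(a50$detect$onsetMin <= sched[5]))
})

test_that("plasticity integrates the post-tetanic windows per layer", {
  # constant 100% gain -> flat 200% trace -> plasticity 100%
  a <- analyzeSession(smallSession(seed = 6, noiseSd = 0,
                                   profile = uniformProfile(100)),
                      doClassify = FALSE)
  expect_equal(a$plasticity$plasticityPct, rep(100, 4), tolerance = 1e-3)
  # biphasic time profile with identical session mean recovers the same value
  b <- analyzeSession(smallSession(seed = 6, noiseSd = 0,
                                   profile = uniformProfile(100, shape = "biphasic")),
                      doClassify = FALSE)
  expect_equal(b$plasticity$plasticityPct, rep(100, 4), tolerance = 1e-3)
})

test_that("voltage variation maps normalize to the array maximum", {
  n <- 1541
  tm <- (seq_len(n) - 1 - 140) / 14
  w <- ifelse(tm > 5 & tm < 30, -100, 0)
  ep1 <- epochsFromWaveforms(rbind(w, w, w), nEpochs = 2)
  vv <- voltageVariationMap(ep1, ep1)
  expect_equal(vv$baseline, rep(1, 3))
  ep2 <- epochsFromWaveforms(rbind(2 * w, w, 0 * w), nEpochs = 2)
  vv2 <- voltageVariationMap(ep2, ep2)
  expect_equal(vv2$baseline, c(1, 0.5, 0))
  epZ <- epochsFromWaveforms(matrix(0, 2, n), nEpochs = 2)
  expect_error(voltageVariationMap(epZ, epZ), "all-silent")
})

test_that("the KS comparison equals a brute-force ECDF computation", {
  expect_equal(compareGroups(1:10, 1:10)$D, 0)
  expect_equal(compareGroups(1:5, 11:15)$D, 1)
  expect_equal(compareGroups(c(1, 2, 3, 4), c(3, 4, 5, 6))$D, 0.5)
  set.seed(8)
  for (i in 1:25) {
    a <- sample(0:20, sample(5:40, 1), replace = TRUE)
    b <- sample(0:20, sample(5:40, 1), replace = TRUE)
    expect_equal(compareGroups(a, b)$D, bruteKsD(a, b), tolerance = 1e-12)
  }
  expect_error(compareGroups(numeric(0), 1:3), "empty")
})
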