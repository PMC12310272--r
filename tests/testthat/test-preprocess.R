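test_that("the SOS band-pass matches the analytic Butterworth response", {
  sos <- butterworthSos(4, 1, 500, 14000)
  freqs <- c(0.5, 1, 5, 22.36, 50, 200, 500, 1000, 5000)
  expect_equal(sosGain(sos, freqs, 14000),
               analyticBandpassGain(freqs, 4, 1, 500, 14000),
               tolerance = 1e-6)
  # unit gain at the geometric mid-band
  expect_equal(sosGain(sos, sqrt(500), 14000), 1, tolerance = 1e-12)
  expect_error(butterworthSos(4, 500, 1, 14000), "low < high")
})

test_that("zero-phase filtering preserves in-band tones and kills out-of-band", {
  cfg <- preprocessConfig()
  t <- (0:83999) / 14000                      # 6 s, measured centrally
  mid <- 30000:54000
  rec50 <- gridRecording(matrix(sin(2 * pi * 50 * t), 1), 14000,
                         gridGeometry(1, 1))
  y50 <- voltages(bandpassFilter(rec50, cfg))[1, ]
  expect_equal(max(y50[mid]), 1, tolerance = 0.01)        # amplitude within 1%
  # zero phase: in-band output tracks the input sample for sample
  expect_equal(y50[mid], sin(2 * pi * 50 * t)[mid], tolerance = 0.012)
  # DC is removed
  recDC <- gridRecording(matrix(100, 1, 84000), 14000, gridGeometry(1, 1))
  yDC <- voltages(bandpassFilter(recDC, cfg))[1, ]
  expect_lt(max(abs(yDC[mid])), 1)
  # 5 kHz attenuated by more than 40 dB
  rec5k <- gridRecording(matrix(sin(2 * pi * 5000 * t), 1), 14000,
                         gridGeometry(1, 1))
  y5k <- voltages(bandpassFilter(rec5k, cfg))[1, ]
  expect_lt(20 * log10(max(abs(y5k[mid]))), -40)
  # Nyquist guard
  expect_error(bandpassFilter(rec50, preprocessConfig(bandHigh = 8000)),
               "Nyquist")
})

test_that("epoch extraction follows the declared alignment conventions", {
  g <- gridGeometry(2, 2)
  rate <- 14000
  vol <- matrix(rep(seq_len(14000), each = 4), 4, 14000, byrow = FALSE)
  cfg <- preprocessConfig(epochPreMs = 5, epochPostMs = 20)
  # 20 test pulses -> 20 epochs
  ev <- data.frame(time = seq(0.05, 0.95, length.out = 20))
  rec <- gridRecording(vol, rate, g, events = ev)
  ep <- extractEpochs(rec, cfg)
  expect_equal(dim(epochArray(ep))[2], 20L)
  expect_true(any(abs(epochTimeMs(ep)) < 1e-12))
  # non-sample-aligned event: onset sample = ceil(time * rate)
  ev2 <- data.frame(time = 0.10005)            # 1400.7 samples
  ep2 <- extractEpochs(gridRecording(vol, rate, g, events = ev2), cfg)
  i0 <- ceiling(0.10005 * rate) + 1            # 1-based index
  expect_equal(epochArray(ep2)[1, 1, which(epochTimeMs(ep2) == 0)], vol[1, i0])
  # HFS trains are excluded from epoching
  ev3 <- rbind(data.frame(time = 0.5, kind = "hfs_train"),
               data.frame(time = seq(0.05, 0.45, length.out = 10),
                          kind = "test_pulse"))
  ep3 <- extractEpochs(gridRecording(vol, rate, g, events = ev3), cfg)
  expect_equal(dim(epochArray(ep3))[2], 10L)
  # window out of range
  expect_error(extractEpochs(gridRecording(vol, rate, g,
               events = data.frame(time = 0.9999)), cfg), "outside")
})

test_that("blanking interpolates the artifact window and centering zeroes the pre-mean", {
  g <- gridGeometry(1, 1)
  rate <- 14000
  cfg <- preprocessConfig(blankMs = 2)
  n <- 4000
  base <- rep(50, n)                       # constant 50 uV
  spike <- base
  spike[round(0.1 * rate) + round(0.0005 * rate)] <- 5000   # spike at 0.5 ms
  mk <- function(v) extractEpochs(gridRecording(matrix(v, 1), rate, g,
                                  events = data.frame(time = 0.1)), cfg)
  epS <- blankAndCenter(mk(spike), cfg)
  epC <- blankAndCenter(mk(base), cfg)
  # spike removed, waveform beyond the blank unchanged; constant -> all zero
  expect_equal(as.numeric(epochArray(epS)), as.numeric(epochArray(epC)),
               tolerance = 1e-12)
  expect_true(all(abs(epochArray(epC)) < 1e-12))
  # pre-stimulus mean is exactly zero after centering
  pre <- epochTimeMs(epS) < 0
  expect_equal(mean(epochArray(epS)[1, 1, pre]), 0, tolerance = 1e-12)
  # blank = 0 leaves the samples untouched
  cfg0 <- preprocessConfig(blankMs = 0)
  ep0 <- blankAndCenter(mk(spike), cfg0)
  expect_equal(max(epochArray(ep0)), 4950, tolerance = 1e-9)
})

test_that("the fused preprocessing path equals the composed operations", {
  set.seed(11)
  g <- gridGeometry(3, 3)
  rec <- gridRecording(matrix(rnorm(9 * 5000), 9), 14000, g,
                       events = data.frame(time = c(0.05, 0.2)))
  cfg <- preprocessConfig()
  a <- preprocessRecording(rec, cfg)
  b <- blankAndCenter(extractEpochs(bandpassFilter(rec, cfg), cfg), cfg)
  expect_equal(a@epochs, b@epochs, tolerance = 1e-12)
  expect_equal(epochTimeMs(a), epochTimeMs(b))
})

test_that("filtering does not shift the detected peak latency", {
  g <- gridGeometry(1, 1)
  rate <- 14000
  tpl <- renderTemplate(waveformTemplate("EPSP", -120, 2, 12), rate, 80)
  v <- numeric(6000)
  onset <- round(0.15 * rate)
  v[onset + seq_along(tpl)] <- tpl
  cfg <- preprocessConfig()
  rec <- gridRecording(matrix(v, 1), rate, g, events = data.frame(time = 0.15))
  epRaw <- blankAndCenter(extractEpochs(rec, cfg), cfg)
  epFilt <- preprocessRecording(rec, cfg)
  pkRaw <- which.min(epochArray(epRaw)[1, 1, ])
  pkFilt <- which.min(epochArray(epFilt)[1, 1, ])
  expect_lt(abs(pkRaw - pkFilt), 2)      # under one sample of shift
})

test_that("epoch windows are independent of which other pulses are cut", {
  set.seed(3)
  g <- gridGeometry(2, 2)
  rec <- gridRecording(matrix(rnorm(4 * 10000), 4), 14000, g,
                       events = data.frame(time = c(0.1, 0.3, 0.5)))
  cfg <- preprocessConfig()
  filt <- bandpassFilter(rec, cfg)
  all3 <- extractEpochs(filt, cfg)
  just2 <- extractEpochs(filt, cfg, events = data.frame(time = c(0.1, 0.5)))
  expect_equal(epochArray(all3)[, c(1, 3), ], epochArray(just2)[, 1:2, ])
})
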