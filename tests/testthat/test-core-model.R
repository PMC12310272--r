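test_that("channel index and grid coordinates are a row-major bijection", {
  g <- gridGeometry()
  pos <- electrodePositions(g)
  expect_equal(nrow(pos), 4096L)
  expect_equal(channelIndex(g, pos$row, pos$col), pos$channel)
  back <- channelPosition(g, pos$channel)
  expect_equal(back$row, pos$row)
  expect_equal(back$col, pos$col)
  # channel 1 at (row 1, col 1) = origin; channel 2 advances along the row
  expect_equal(pos$x[1:2], c(0, 42))
  expect_equal(pos$y[1:2], c(0, 0))
  expect_false(any(duplicated(pos[, c("x", "y")])))
})

test_that("recording validity rejects inconsistent objects", {
  g <- gridGeometry(2, 5)
  vol <- matrix(0, 10, 50)
  expect_s4_class(gridRecording(vol, 1000, g), "GridRecording")
  # event beyond trace end
  expect_error(gridRecording(vol, 1000, g, events = data.frame(time = 1)),
               "outside the recorded trace")
  # negative intensity, inadmissible half-width
  expect_error(gridRecording(vol, 1000, g,
               events = data.frame(time = 0.01, intensity = -1)), "intensity")
  expect_error(gridRecording(vol, 1000, g,
               events = data.frame(time = 0.01, half_width_us = 50)),
               "half-width")
  expect_error(gridRecording(matrix(NaN, 10, 5), 1000, g), "finite")
})

test_that("layer maps enforce network-consistent labels", {
  expect_error(layerMap(rep("ML", 10), "CA"), "CA networks")
  expect_error(layerMap(rep("SO", 10), "DG"), "DG networks")
  lm <- layerMap(c(rep("SO", 5), rep("none", 5)), "CA")
  expect_equal(sum(layerLabels(lm) == "SO"), 5L)
})

test_that("the session container round-trips all fields", {
  set.seed(42)
  g <- gridGeometry(2, 5)
  vol <- matrix(rnorm(10 * 100), 10, 100)
  ev <- data.frame(time = c(0.01, 0.05), intensity = c(50, 50),
                   half_width_us = 100, site_x = 42, site_y = 0,
                   kind = "test_pulse", nominal_min = c(-1, -0.5))
  rec <- gridRecording(vol, rate = 1000, geometry = g, events = ev,
                       phase = "baseline", t0 = 0)
  lm <- layerMap(c(rep("SR", 5), rep("none", 5)), "CA")
  path <- file.path(tempdir(), "toy-session")
  saveRecording(rec, lm, path)
  back <- loadRecording(path)
  expect_identical(voltages(back$recording), vol)   # bit-exact
  expect_equal(stimulusEvents(back$recording), ev)
  expect_identical(as.character(layerLabels(back$layers)),
                   as.character(layerLabels(lm)))
  expect_identical(sampleRate(back$recording), 1000)
  expect_identical(recordingPhase(back$recording), "baseline")
  unlink(path, recursive = TRUE)
})

test_that("an I/O sweep of 12 pulses at 30 s spacing round-trips its schedule", {
  g <- gridGeometry(2, 5)
  times <- seq(0, 330, by = 30)
  rec <- gridRecording(matrix(0, 10, 35000), rate = 100, geometry = g,
                       events = data.frame(time = times,
                                           intensity = seq(20, 130, 10)),
                       phase = "io_sweep")
  path <- file.path(tempdir(), "io-session")
  saveRecording(rec, layerMap(rep("none", 10), "CA"), path)
  back <- loadRecording(path)
  expect_identical(stimulusEvents(back$recording)$time, times)
  unlink(path, recursive = TRUE)
})

test_that("the container refuses truncated or unknown-version files", {
  g <- gridGeometry(2, 5)
  rec <- gridRecording(matrix(0, 10, 20), rate = 1000, geometry = g)
  lm <- layerMap(rep("none", 10), "CA")
  path <- file.path(tempdir(), "bad-session")
  saveRecording(rec, lm, path)
  # truncate the voltage payload
  writeBin(rep(0, 5), file.path(path, "voltages.f64"), size = 8)
  expect_error(loadRecording(path), "truncated|schema")
  saveRecording(rec, lm, path)
  meta <- jsonlite::read_json(file.path(path, "meta.json"))
  meta$schema_version <- "9.9"
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE)
  expect_error(loadRecording(path), "unknown container schema version")
  expect_error(loadRecording(file.path(tempdir(), "does-not-exist")),
               "schema error")
  unlink(path, recursive = TRUE)
})

test_that("saveSession/loadSession restores a simulated session with truth", {
  s <- smallSession(seed = 7, noiseSd = 5,
                    phases = c("baseline", "post_tetanic"))
  path <- file.path(tempdir(), "full-session")
  saveSession(s, path)
  back <- loadSession(path)
  expect_identical(voltages(back$baseline), voltages(s$baseline))
  expect_identical(voltages(back$post_tetanic), voltages(s$post_tetanic))
  expect_equal(back$truth$clusters$fold, s$truth$clusters$fold)
  expect_equal(back$truth$electrodes$peakLatencyBaseMs,
               s$truth$electrodes$peakLatencyBaseMs)
  expect_identical(network(back$layers), "CA")
  unlink(path, recursive = TRUE)
})
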