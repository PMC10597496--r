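test_that("the determinism sweep covers its grid reproducibly", {
  m <- pointModel("base")
  lib <- sampleRandomFrames(base_trace(), 25, seed = 13)
  sw <- determinismSweep(m, n_patterns = 4, k_frames = 25,
                         n_values = c(3, 5), seed = 21,
                         frame_library = lib)
  expect_equal(nrow(sw$summary), 4 * 2)
  expect_setequal(sw$summary$n, c(3, 5))
  expect_equal(length(sw$distributions), 8)
  expect_true(all(vapply(sw$distributions, kResponses, 1L) == 25))

  sw2 <- determinismSweep(m, n_patterns = 4, k_frames = 25,
                          n_values = c(3, 5), seed = 21,
                          frame_library = lib)
  expect_identical(sw$summary, sw2$summary)

  expect_error(determinismSweep(m, k_frames = 1), "k_frames")
  expect_error(determinismSweep(m, n_patterns = 2, k_frames = 25,
                                n_values = 60, pattern_events = 50,
                                frame_library = lib),
               "exceed")
})

test_that("replication runs share stimuli with ground truth and validate n", {
  m <- pointModel("base")
  expect_error(replicationExperiment(m, n_values = 0), "window sizes")
  r <- replicationExperiment(m, duration = 2000, n_values = 3, seed = 5,
                             library_duration = 20000)
  expect_gt(length(r$truth), 10)
  expect_true(all(r$trains[["3"]] <= 2000))
  expect_true(all(diff(r$trains[["3"]]) > 0))
  expect_gte(r$summary$van_rossum, 0)
  r2 <- replicationExperiment(m, duration = 2000, n_values = 3, seed = 5,
                              library_duration = 20000)
  expect_identical(r$summary, r2$summary)
})

test_that("reconstruction error is zero for identical initializations", {
  m <- pointModel("base")
  fr <- extractSpikingFrames(base_trace())
  twin <- new("FrameLibrary",
              frames = frameMatrix(fr)[c(1, 1), ], kind = "SPIKING",
              seed = NA_integer_, model = "base")
  rec <- reconstructionExperiment(m, n_pairs = 3, duration = 50, seed = 8,
                                  spiking_library = twin)
  expect_true(all(rec$mae == 0))

  one <- new("FrameLibrary", frames = frameMatrix(fr)[1, , drop = FALSE],
             kind = "SPIKING", seed = NA_integer_, model = "base")
  expect_error(reconstructionExperiment(m, spiking_library = one),
               "at least 2")
  expect_error(reconstructionExperiment(m, n_pairs = 1), "n_pairs")
})

test_that("reconstruction offsets are uniform and error is non-negative", {
  m <- pointModel("base")
  lib <- extractSpikingFrames(base_trace())
  rec <- reconstructionExperiment(m, n_pairs = 20, duration = 60, seed = 9,
                                  spiking_library = lib)
  expect_equal(unique(round(diff(rec$offsets), 10)), 0.025)
  expect_true(all(rec$mae >= 0))
  expect_gt(max(rec$mae), 0)
})

test_that("the variance summary is seed-stable and demands enough spikes", {
  s1 <- spikeVarianceSummary(models = "base", duration = 8000, seed = 14,
                             min_spikes = 50)
  s2 <- spikeVarianceSummary(models = "base", duration = 8000, seed = 14,
                             min_spikes = 50)
  expect_identical(s1, s2)
  expect_true(s1$pct_of_baseline > 0 && s1$pct_of_baseline < 100)
  expect_error(spikeVarianceSummary(models = "base", duration = 2000,
                                    seed = 14, min_spikes = 10000),
               "insufficient")
})
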