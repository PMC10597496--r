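test_that("the scheduler commits, invalidates and bounds predictions", {
  st <- eventHistory(c(0, 10, 20, 30, 40), "exc")
  expect_length(runOnEventSim(st, function(w) Inf, n = 3), 0)
  expect_equal(runOnEventSim(st, function(w) 1, n = 3),
               c(1, 11, 21, 31, 41))
  # each earlier prediction invalidated by the next stimulus
  fast <- eventHistory(c(0, 2, 4, 6, 8), "exc")
  expect_equal(runOnEventSim(fast, function(w) 5, n = 3), 13)
  # t_end truncates trailing predictions
  expect_length(runOnEventSim(fast, function(w) 5, n = 3, t_end = 10), 0)

  expect_error(runOnEventSim(st, function(w) 0, n = 3), "NST <= 0")
  expect_error(runOnEventSim(st, function(w) "a", n = 3), "numeric")
  expect_error(runOnEventSim(st, function(w) 1, n = 0), "n must be")
  sp <- eventHistory(c(1, 2), c("exc", "spike"))
  expect_error(runOnEventSim(sp, function(w) 1, n = 2), "output-spike")
})

test_that("windows hold the n most recent events, all during cold start", {
  st <- eventHistory(c(0, 10, 20, 30, 40), "exc")
  seen <- list()
  fn <- function(w) { seen[[length(seen) + 1L]] <<- w; Inf }
  runOnEventSim(st, fn, n = 3)
  expect_equal(vapply(seen, length, 1L), c(1L, 2L, 3L, 3L, 3L))
  expect_equal(eventTimes(seen[[5]]), c(20, 30, 40))
  # the last window entry is always the triggering event
  for (i in seq_along(seen))
    expect_equal(max(eventTimes(seen[[i]])), eventTimes(st)[i])
})

test_that("output-spike feedback truncates windows at the last spike", {
  st <- eventHistory(c(0, 10, 20, 30, 40), "exc")
  seen <- list()
  fn <- function(w) { seen[[length(seen) + 1L]] <<- w; 5 }
  got <- runOnEventSim(st, fn, n = 4, include_output_spikes = TRUE)
  expect_equal(got, c(5, 15, 25, 35, 45))
  # from the second stimulus on, the window starts at the previous spike
  for (i in 2:5) {
    w <- seen[[i]]
    expect_equal(eventLabels(w)[1], "spike")
    expect_equal(eventTimes(w), c(eventTimes(st)[i] - 5, eventTimes(st)[i]))
  }
  # recorded spikes are strictly increasing and never closer than allowed
  expect_true(all(diff(got) > 0))
})

test_that("the conductance oracle respects initialization, inhibition and determinism", {
  m <- pointModel("base")
  lib <- frame_library_of(m, restingFrame(m))
  fn <- conductanceOracle(m, lib, mode = "MEDIAN_FRAME")
  # inhibition alone can never cross 0 mV
  expect_identical(fn(eventHistory(c(0, 5, 9), "inh")), Inf)
  # deterministic in MEDIAN_FRAME mode
  w <- makePattern(10, seed = 31)
  expect_identical(fn(w), fn(w))
  expect_error(fn(eventHistory()), "empty event window")
  expect_error(conductanceOracle(m, lib, extension = 0), "extension")
  # spike-start windows demand a spiking library
  sw <- eventHistory(c(0, 3), c("spike", "exc"))
  expect_error(fn(sw), "spiking frame")
})

test_that("RANDOM_FRAME draws are seed-reproducible and leave the global RNG alone", {
  tr <- base_trace()
  lib <- sampleRandomFrames(tr, 50, seed = 12)
  spik <- extractSpikingFrames(tr)
  w <- makePattern(8, seed = 33)
  f1 <- conductanceOracle(pointModel("base"), lib, spik,
                          mode = "RANDOM_FRAME", seed = 5)
  f2 <- conductanceOracle(pointModel("base"), lib, spik,
                          mode = "RANDOM_FRAME", seed = 5)
  set.seed(77)
  before <- .Random.seed
  r1 <- c(f1(w), f1(w), f1(w))
  expect_identical(before, .Random.seed)
  expect_identical(r1, c(f2(w), f2(w), f2(w)))
})

test_that("full-history windows from the true state reproduce the continuous run", {
  m <- pointModel("base")
  sizes <- c(12, 18, 23, 27, 30)
  for (s in 1:5) {
    pat <- makePattern(sizes[s], seed = 200 + s)
    horizon <- max(eventTimes(pat)) + 50
    truth <- traceSpikes(simulateModel(m, pat, t_end = horizon))
    lib <- frame_library_of(m, restingFrame(m))
    fn <- conductanceOracle(m, lib, mode = "MEDIAN_FRAME",
                            extension = horizon)
    pred <- runOnEventSim(pat, fn, n = length(pat), t_end = horizon)
    expect_length(pred, length(truth))
    if (length(truth))
      expect_lt(max(abs(pred - truth)), 0.025 + 1e-9)
  }
})

test_that("ground-truth runs validate duration and reproduce exactly", {
  m <- pointModel("base")
  st <- mergeEvents(poissonStream(10, 2000, "exc", 41),
                    poissonStream(10, 2000, "inh", 42))
  expect_error(groundTruthRun(m, st, 0), "duration")
  a <- groundTruthRun(m, st, 2000, record = FALSE)
  b <- groundTruthRun(m, st, 2000, record = FALSE)
  expect_gt(length(traceSpikes(a)), 0)
  expect_identical(traceSpikes(a), traceSpikes(b))
})
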