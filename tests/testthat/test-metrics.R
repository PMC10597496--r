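test_that("spiking ratio and coherence follow their closed forms", {
  expect_equal(spikingRatio(responseDistribution(c(1, 2, 3))), 1)
  expect_equal(spikingRatio(responseDistribution(rep(Inf, 4))), 0)
  d <- responseDistribution(c(runif(670, 1, 10), rep(Inf, 330)))
  expect_equal(spikingRatio(d), 0.67)
  expect_equal(spikePredictionCoherence(d), 0.67^2 + 0.33^2)

  expect_equal(spikePredictionCoherence(responseDistribution(c(1, 2))), 1)
  expect_equal(spikePredictionCoherence(responseDistribution(c(1, Inf))), 0.5)
  # r = 0.82 (100 responses, 82 spiking)
  d82 <- responseDistribution(c(runif(82, 1, 5), rep(Inf, 18)))
  expect_equal(spikePredictionCoherence(d82), 0.7048)
})

test_that("coherence is bounded and symmetric in the spiking ratio", {
  withr::with_seed(1, {
    for (i in 1:1000) {
      k <- sample(2:50, 1)
      nst <- ifelse(runif(k) < runif(1), Inf, runif(k, 0.1, 30))
      coh <- spikePredictionCoherence(responseDistribution(pmax(nst, 0.1)))
      expect_gte(coh, 0.5)
      expect_lte(coh, 1)
    }
  })
  r <- seq(0, 1, by = 0.01)
  expect_equal(r^2 + (1 - r)^2, rev(r^2 + (1 - r)^2))
})

test_that("NST dispersion uses finite responses only, sample denominator", {
  expect_equal(nstStd(responseDistribution(rep(2.5, 10))), 0)
  expect_equal(nstStd(responseDistribution(c(1, 3))), sqrt(2))
  expect_equal(nstStd(responseDistribution(c(1, 3, Inf, Inf))), sqrt(2))
  expect_true(is.na(nstStd(responseDistribution(c(4, Inf)))))
})

test_that("determinism categories partition the response space", {
  expect_equal(classifyResponseSet(responseDistribution(rep(Inf, 1000))),
               "DET_NONSPIKING")
  expect_equal(classifyResponseSet(responseDistribution(rep(5, 100) +
                                     rnorm(100, 0, 0.01))), "DET_SPIKING")
  expect_equal(classifyResponseSet(responseDistribution(runif(100, 1, 20))),
               "NONDET_SPIKING")
  expect_equal(classifyResponseSet(responseDistribution(
    c(runif(50, 1, 5), rep(Inf, 50)))), "NONDET")
  # boundaries: the printed thresholds are strict for determinism
  half <- responseDistribution(c(rep(1, 99), Inf))           # r = 0.99
  expect_equal(classifyResponseSet(half), "DET_SPIKING")
  jit <- responseDistribution(c(seq(1, 1.4, length.out = 99), Inf))
  expect_equal(classifyResponseSet(jit), "NONDET_SPIKING")
  low <- responseDistribution(c(rep(Inf, 995), rep(1, 5)))   # r = 0.005
  expect_equal(classifyResponseSet(low), "DET_NONSPIKING")
  # every random distribution lands in exactly one category
  withr::with_seed(2, {
    cats <- replicate(200, {
      k <- sample(c(3, 100, 1000), 1)
      nst <- ifelse(runif(k) < runif(1), Inf, rexp(k, 1 / 5) + 0.1)
      classifyResponseSet(responseDistribution(nst))
    })
    expect_true(all(cats %in% c("DET_NONSPIKING", "DET_SPIKING",
                                "NONDET_SPIKING", "NONDET")))
  })
})

test_that("van Rossum distance matches its closed forms and metric axioms", {
  expect_equal(vanRossumDistance(c(1, 5, 9), c(1, 5, 9)), 0)
  expect_equal(vanRossumDistance(5, numeric(), tau = 10), sqrt(0.5))
  expect_equal(vanRossumDistance(0, 10, tau = 10), sqrt(1 - exp(-1)))
  expect_equal(vanRossumDistance(0, 7, tau = 3.5),
               sqrt(1 - exp(-2)))
  expect_error(vanRossumDistance(-1, 2), "non-negative")
  expect_error(vanRossumDistance(1, 2, tau = 0), "tau")

  withr::with_seed(3, {
    for (i in 1:100) {
      tr <- lapply(1:3, function(j) sort(runif(sample(0:8, 1), 0, 50)))
      dab <- vanRossumDistance(tr[[1]], tr[[2]])
      dba <- vanRossumDistance(tr[[2]], tr[[1]])
      dac <- vanRossumDistance(tr[[1]], tr[[3]])
      dcb <- vanRossumDistance(tr[[3]], tr[[2]])
      expect_equal(dab, dba)
      expect_lte(dab, dac + dcb + 1e-12)  # triangle inequality
    }
  })
})

test_that("closed-form van Rossum agrees with numerical filtering", {
  num_vr <- function(a, b, tau) {
    dt <- 0.001
    tt <- seq(0, 80, by = dt)
    filt <- function(s) Reduce(`+`, lapply(s, function(t0)
      ifelse(tt >= t0, exp(-(tt - t0) / tau), 0)), accumulate = FALSE,
      init = numeric(length(tt)))
    sqrt(sum((filt(a) - filt(b))^2) * dt / tau)
  }
  withr::with_seed(4, {
    for (i in 1:5) {
      a <- sort(runif(4, 0, 30)); b <- sort(runif(3, 0, 30))
      expect_equal(vanRossumDistance(a, b, tau = 8), num_vr(a, b, 8),
                   tolerance = 1e-2)
    }
  })
})

test_that("ISI histograms conserve counts and recover exponential intervals", {
  h <- isiDistribution(c(0, 10, 20), bin_width = 1)
  expect_equal(h$isis, c(10, 10))
  expect_equal(sum(h$counts), 2)
  expect_length(isiDistribution(5)$isis, 0)

  s <- eventTimes(poissonStream(15, 60000, "exc", seed = 6))
  h2 <- isiDistribution(s)
  expect_equal(sum(h2$counts), length(s) - 1)
  ks <- suppressWarnings(ks.test(h2$isis, "pexp", rate = 1 / 15))
  expect_gt(ks$p.value, 0.01)
})

test_that("spike matching agrees with the brute-force all-pairs check", {
  expect_true(all(matchSpikes(c(1, 2, 3), c(1, 2, 3))$matched))
  expect_false(matchSpikes(5.0, 6.5, tol = 1)$matched)
  withr::with_seed(7, {
    for (i in 1:20) {
      pred <- sort(runif(50, 0, 1000))
      truth <- sort(runif(50, 0, 1000))
      got <- matchSpikes(pred, truth, tol = 1)
      brute <- vapply(pred, function(p) any(abs(truth - p) <= 1), TRUE)
      expect_identical(got$matched, brute)
      expect_equal(got$n_matched + got$n_unmatched, 50)
    }
  })
})

test_that("spike-triggered variance matches a naive two-pass computation", {
  # constant trace: zero variance everywhere
  tr0 <- synthetic_trace(rep(-65, 5000))
  v0 <- spikeTriggeredVariance(tr0, window = 5,
                               spikes = c(100, 200, 300, 400))
  expect_true(all(v0$variance == 0))
  expect_equal(v0$summary$min_ratio, 0)

  # windows that are copies of one waveform
  wave <- rep(sin(seq(0, 2 * pi, length.out = 100)), 50)
  trw <- synthetic_trace(wave)
  vw <- spikeTriggeredVariance(trw, window = 2,
                               spikes = seq(50, 4900, by = 100) * 0.1)
  expect_true(all(vw$variance[, "vm"] < 1e-20))

  # random trace vs naive computation
  withr::with_seed(8, vm <- rnorm(6000))
  trr <- synthetic_trace(vm)
  sp <- seq(30, 560, by = 11)  # 49 windows
  got <- spikeTriggeredVariance(trr, window = 1, spikes = sp)
  half <- round(1 / 0.1)
  centers <- round(sp / 0.1) + 1
  naive <- sapply(seq(-half, half), function(o)
    var(vm[centers + o]))
  expect_equal(unname(got$variance[, "vm"]), naive)
  expect_equal(got$baseline[["vm"]], var(vm))

  expect_error(spikeTriggeredVariance(trr, window = 1, spikes = 3,
                                      min_windows = 2), "insufficient")
})

test_that("transition analysis tallies and attributes newly included stimuli", {
  hs <- lapply(1:3, function(i) makePattern(12, seed = 500 + i))
  const <- matrix("NONDET", 3, 4, dimnames = list(NULL, 5:8))
  ta <- transitionAnalysis(const, hs)
  expect_true(all(ta$tallies$from == ta$tallies$to))
  expect_equal(nrow(ta$transitions), 0)

  # a hand-built switch at n = 9 -> 10 is attributed to the 10th most
  # recent stimulus, with its interval to the 9th most recent
  h <- eventHistory(seq(0, 110, by = 10), rep("exc", 12))
  cats <- matrix(c("NONDET", "DET_SPIKING"), 1, 2,
                 dimnames = list(NULL, 9:10))
  ta2 <- transitionAnalysis(cats, list(h))
  expect_equal(nrow(ta2$transitions), 1)
  expect_equal(ta2$transitions$n_from, 9)
  # 10th most recent of 12 is event index 3; interval to index 4 is 10 ms
  expect_equal(ta2$transitions$isi, 10)
  expect_equal(ta2$transitions$label, "exc")

  # tallies match a brute-force recount over random category sequences
  withr::with_seed(9, {
    levs <- c("DET_NONSPIKING", "DET_SPIKING", "NONDET_SPIKING", "NONDET")
    cats <- matrix(sample(levs, 100 * 6, replace = TRUE), 100, 6,
                   dimnames = list(NULL, 3:8))
    hs <- lapply(1:100, function(i) makePattern(10, seed = 2000 + i))
    ta3 <- transitionAnalysis(cats, hs)
    for (j in 1:5) {
      pairs <- table(paste(cats[, j], cats[, j + 1]))
      sub <- ta3$tallies[ta3$tallies$n_from == (3:8)[j], ]
      expect_equal(sum(sub$count), 100)
      expect_equal(sub$count[order(paste(sub$from, sub$to))],
                   as.integer(pairs[sort(names(pairs))]))
    }
  })
  expect_error(transitionAnalysis(const, hs[1:2]), "one history per")
})
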