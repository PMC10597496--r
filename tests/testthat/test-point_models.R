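test_that("gating rates match closed forms and fill removable singularities", {
  r <- gatingRates(-40, "HH")
  expect_equal(r$alpha_m, 1.0, tolerance = 1e-9)
  # continuity across the singularity
  expect_equal(gatingRates(-40 + 1e-7, "HH")$alpha_m, 1.0, tolerance = 1e-6)
  expect_equal(gatingRates(-65, "HH")$beta_m, 4.0)
  expect_equal(gatingRates(-65, "HH")$alpha_m, 0.2236, tolerance = 1e-3)
  g <- steadyStateGates(-65, "HH")
  expect_equal(unname(g["m"]), 0.0529, tolerance = 1e-3)

  for (kind in c("HH", "WB")) {
    rr <- gatingRates(seq(-100, 60, by = 0.5), kind)
    for (v in rr) expect_true(all(v >= 0 & is.finite(v)))
  }
  expect_error(gatingRates(NaN, "HH"), "finite")
})

test_that("derivatives vanish at the resting fixed point and at reversal", {
  for (name in c("base", "wb")) {
    m <- pointModel(name)
    # locate the fixed point: dVm = 0 with gates at steady state
    f <- function(v) {
      fr <- restingFrame(m, v)
      membraneDerivatives(m, fr)[["dvm"]]
    }
    vs <- seq(-80, -50, by = 0.5)
    fv <- vapply(vs, f, numeric(1))
    i <- which(diff(sign(fv)) != 0)[1]
    v_star <- uniroot(f, vs[c(i, i + 1)], tol = 1e-12)$root
    d <- membraneDerivatives(m, restingFrame(m, v_star))
    expect_true(all(abs(d) < 1e-6))
  }
  # at Vm = e_exc the excitatory synaptic current is zero
  m <- pointModel("base")
  fr <- restingFrame(m)
  fr["vm"] <- m@e_exc
  d0 <- membraneDerivatives(m, fr, g_exc = 0)
  d1 <- membraneDerivatives(m, fr, g_exc = 0.01)
  expect_equal(d1[["dvm"]], d0[["dvm"]])
})

test_that("specific-conductance dynamics are invariant to area when weights scale", {
  st <- eventHistory(c(3, 8, 15, 21), c("exc", "exc", "inh", "exc"))
  m1 <- pointModel("base")
  m2 <- pointModel("base", area = 2 * m1@area,
                   weight_exc = 2 * m1@weight_exc,
                   weight_inh = 2 * m1@weight_inh)
  t1 <- simulateModel(m1, st, t_end = 60)
  t2 <- simulateModel(m2, st, t_end = 60)
  expect_equal(traceVm(t1), traceVm(t2), tolerance = 1e-12)
  expect_equal(traceSpikes(t1), traceSpikes(t2), tolerance = 1e-12)
})

test_that("integration is quiescent at rest, deterministic, and spikes to strong input", {
  m <- pointModel("base")
  tr <- simulateModel(m, t_end = 1000)
  expect_length(traceSpikes(tr), 0)
  expect_true(max(abs(traceVm(tr) + 65)) < 0.5)  # stays near rest

  strong <- pointModel("base", weight_exc = 20 * m@weight_exc)
  tr2 <- simulateModel(strong, eventHistory(10, "exc"), t_end = 60)
  expect_length(traceSpikes(tr2), 1)
  expect_lt(abs(traceSpikes(tr2) - 10), 5)

  st <- mergeEvents(poissonStream(10, 500, "exc", 4),
                    poissonStream(10, 500, "inh", 5))
  a <- simulateModel(m, st, t_end = 500)
  b <- simulateModel(m, st, t_end = 500)
  expect_identical(traceSpikes(a), traceSpikes(b))

  # gating variables stay within [0, 1] on every integrated trajectory
  for (trace in list(tr, tr2, a)) {
    expect_true(all(trace@gates >= 0 & trace@gates <= 1))
  }
})

test_that("halving dt moves spike times by less than 0.1 ms", {
  m <- pointModel("base")
  st <- mergeEvents(poissonStream(10, 500, "exc", 21),
                    poissonStream(10, 500, "inh", 22))
  s1 <- traceSpikes(simulateModel(m, st, t_end = 500, dt = 0.025))
  s2 <- traceSpikes(simulateModel(m, st, t_end = 500, dt = 0.0125))
  expect_gt(length(s1), 3)
  expect_length(s2, length(s1))
  expect_lt(max(abs(s1 - s2)), 0.1)
})

test_that("event validation rejects unsorted or out-of-window input", {
  m <- pointModel("base")
  # the EventHistory class itself guarantees ordering
  expect_error(new("EventHistory", time = c(10, 5),
                   label = c("exc", "exc")), "non-decreasing")
  late <- eventHistory(80, "exc")
  expect_error(simulateModel(m, late, t_end = 50), "within")
  expect_error(simulateModel(m, t_end = 50, dt = -1), "dt")
})

test_that("spike detection interpolates crossings and ignores subthreshold traces", {
  expect_equal(detectSpikes(c(-10, 10), c(0, 1)), 0.5)
  expect_length(detectSpikes(c(-5, -1, -0.01), 0:2), 0)
  expect_error(detectSpikes(5, 0), "2 samples")

  # sine crossing zero upward at t = 5 and t = 25 (period 20 ms)
  tt <- seq(0, 40, by = 0.1)
  vm <- sin(2 * pi * (tt - 5) / 20)
  got <- detectSpikes(vm, tt)
  expect_length(got, 2)
  expect_equal(got, c(5, 25), tolerance = 0.1)
})
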