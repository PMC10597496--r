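# Seeded experiment drivers: the single-spike determinism sweep, the
# extended replication comparison, state-variable reconstruction, and
# the spike-triggered variance summary.

# Derive independent sub-seeds (< 2^31) from one master seed.
.sub_seeds <- function(seed, k) {
  withr::with_seed(as.integer(seed),
                   sample.int(.Machine$integer.max - 1L, k))
}

#' Sweep response determinism over window sizes
#'
#' For each of `n_patterns` fixed stimulus patterns and each window size
#' in `n_values`, evaluates the conductance oracle once per frame of a
#' random-frame library (each frame is one initialization) on the last
#' `n` events of the pattern, and records the resulting
#' next-spike-time distribution, its spiking ratio, spike prediction
#' coherence, NST standard deviation and determinism category. Fully
#' reproducible from `seed`.
#'
#' @param model a [PointModel-class].
#' @param n_patterns number of stimulus patterns.
#' @param k_frames number of random initialization frames (>= 2).
#' @param n_values window sizes; all must be at most `pattern_events`.
#' @param seed master seed.
#' @param pattern_events events per full pattern.
#' @param exc_interval,inh_interval stimulus stream parameters (ms).
#' @param extension oracle integration extension (ms).
#' @param dt integration step (ms).
#' @param frame_library optional pre-built random [FrameLibrary-class];
#'   by default one is sampled from a fresh ground-truth run of
#'   `source_duration` ms.
#' @param source_duration duration (ms) of the ground-truth run behind
#'   the default frame library.
#' @return list of class `"onevent_sweep"` with `summary` (data.frame:
#'   `pattern_id`, `n`, `spiking_ratio`, `coherence`, `nst_std`,
#'   `category`), `distributions` (list of
#'   [ResponseDistribution-class]), `patterns` (the EventHistory list),
#'   `model`, `k`, `n_values`, `seed`.
#' @export
determinismSweep <- function(model, n_patterns = 50, k_frames = 100,
                             n_values = c(3, 5, 10, 15, 25, 50),
                             seed = 1, pattern_events = max(n_values),
                             exc_interval = 10, inh_interval = 10,
                             extension = 20, dt = 0.025,
                             frame_library = NULL,
                             source_duration = 100000) {
  stopifnot(is(model, "PointModel"))
  if (k_frames < 2) stop("k_frames must be >= 2")
  n_values <- sort(unique(as.integer(n_values)))
  if (max(n_values) > pattern_events)
    stop("window sizes exceed the number of events per pattern")
  seeds <- .sub_seeds(seed, n_patterns + 2L)

  if (is.null(frame_library)) {
    stim <- mergeEvents(
      poissonStream(exc_interval, source_duration, "exc", seeds[1]),
      poissonStream(inh_interval, source_duration, "inh", seeds[2]))
    src <- groundTruthRun(model, stim, source_duration, dt = dt)
    frame_library <- sampleRandomFrames(src, k_frames, seed = seeds[1])
  }
  fmat <- .frame_matrix4(model, frameMatrix(frame_library))
  params <- .model_params(model)

  patterns <- lapply(seq_len(n_patterns), function(i)
    makePattern(pattern_events, exc_interval, inh_interval,
                seed = seeds[i + 2L]))

  rows <- vector("list", n_patterns * length(n_values))
  dists <- vector("list", n_patterns * length(n_values))
  r <- 0L
  for (p in seq_len(n_patterns)) {
    tt <- eventTimes(patterns[[p]])
    ll <- eventLabels(patterns[[p]])
    len <- length(tt)
    for (n in n_values) {
      w <- (len - n + 1):len
      rel <- tt[w] - tt[w][1]
      t_last <- rel[n]
      nsts <- .cpp_batch_nst(params, fmat, rel,
                             as.integer(ll[w] == "exc"),
                             t_last, t_last + extension, dt)
      d <- responseDistribution(nsts, pattern_id = p, n_window = n)
      r <- r + 1L
      dists[[r]] <- d
      rows[[r]] <- data.frame(
        pattern_id = p, n = n, spiking_ratio = spikingRatio(d),
        coherence = spikePredictionCoherence(d), nst_std = nstStd(d),
        category = classifyResponseSet(d))
    }
  }
  structure(list(summary = do.call(rbind, rows), distributions = dists,
                 patterns = patterns, model = model@name,
                 k = nrow(fmat), n_values = n_values, seed = seed),
            class = "onevent_sweep")
}

#' Replicate an extended simulation from limited event windows
#'
#' Runs a ground-truth continuous simulation and, over the identical
#' stimulus stream, on-event simulations whose oracle re-runs the model
#' from the median state-variable frame (or, when the window starts at
#' an output spike, the spiking-library medoid). Per window size the
#' resulting spike train is compared to ground truth by van Rossum
#' distance (raw and per ground-truth spike) and by ISI histogram.
#'
#' @param model a [PointModel-class].
#' @param duration simulated span (ms); at least ~1000 ms for meaningful
#'   statistics.
#' @param n_values window sizes (each >= 1).
#' @param include_output_spikes feed output spikes back into the windows
#'   (see [runOnEventSim()]).
#' @param seed master seed.
#' @param exc_interval,inh_interval stimulus stream parameters (ms).
#' @param extension oracle integration extension (ms).
#' @param tau_vr van Rossum kernel time constant (ms).
#' @param dt integration step (ms).
#' @param library_duration duration (ms) of the separate run behind the
#'   frame libraries.
#' @return list of class `"onevent_replication"`: `summary` (data.frame
#'   `n`, `n_spikes`, `van_rossum`, `van_rossum_per_spike`), `trains`
#'   (per-n spike-time vectors), `truth` (ground-truth spike times),
#'   `isis` (per-n ISI vectors), `truth_isis`, `model`, `seed`,
#'   `include_output_spikes`.
#' @export
replicationExperiment <- function(model, duration = 10000,
                                  n_values = c(3, 10, 25, 40),
                                  include_output_spikes = FALSE, seed = 1,
                                  exc_interval = 10, inh_interval = 10,
                                  extension = 20, tau_vr = 10, dt = 0.025,
                                  library_duration = 100000) {
  stopifnot(is(model, "PointModel"))
  n_values <- as.integer(n_values)
  if (any(n_values < 1)) stop("window sizes must be >= 1")
  seeds <- .sub_seeds(seed, 4L)

  lib_stim <- mergeEvents(
    poissonStream(exc_interval, library_duration, "exc", seeds[1]),
    poissonStream(inh_interval, library_duration, "inh", seeds[2]))
  src <- groundTruthRun(model, lib_stim, library_duration, dt = dt)
  rand_lib <- sampleRandomFrames(src, 1000, seed = seeds[1])
  spik_lib <- extractSpikingFrames(src)

  stim <- mergeEvents(
    poissonStream(exc_interval, duration, "exc", seeds[3]),
    poissonStream(inh_interval, duration, "inh", seeds[4]))
  truth <- traceSpikes(groundTruthRun(model, stim, duration, dt = dt,
                                      record = FALSE))
  fn <- conductanceOracle(model, rand_lib, spik_lib,
                          mode = "MEDIAN_FRAME", extension = extension,
                          dt = dt)
  trains <- lapply(n_values, function(n)
    runOnEventSim(stim, fn, n, include_output_spikes, t_end = duration))
  names(trains) <- n_values
  summary <- do.call(rbind, lapply(seq_along(n_values), function(i) {
    vr <- vanRossumDistance(trains[[i]], truth, tau = tau_vr)
    data.frame(n = n_values[i], n_spikes = length(trains[[i]]),
               van_rossum = vr,
               van_rossum_per_spike = vr / max(1L, length(truth)))
  }))
  structure(list(summary = summary, trains = trains, truth = truth,
                 isis = lapply(trains, function(tr) isiDistribution(tr)$isis),
                 truth_isis = isiDistribution(truth)$isis,
                 model = model@name, seed = seed,
                 include_output_spikes = include_output_spikes),
            class = "onevent_replication")
}

#' Reconstructability of the membrane potential from events alone
#'
#' Simulates pairs of runs that share an identical stimulus stream but
#' start from two randomly chosen (distinct-index) spiking frames, and
#' measures the mean absolute difference in membrane potential as a
#' function of time since the start. Decay of this curve means the
#' state is progressively pinned down by the ongoing events, despite
#' unknown initial conditions.
#'
#' @param model a [PointModel-class].
#' @param n_pairs number of simulation pairs (>= 2).
#' @param duration pair duration (ms).
#' @param seed master seed.
#' @param spiking_library optional [FrameLibrary-class] of spiking
#'   frames (>= 2 frames); built from a fresh ground-truth run by
#'   default.
#' @param exc_interval,inh_interval stimulus stream parameters (ms).
#' @param dt integration step (ms).
#' @param library_duration duration (ms) of the default library run.
#' @return list of class `"onevent_reconstruction"`: `offsets` (ms),
#'   `mae` (mV, per offset), `n_pairs`, `model`, `seed`.
#' @export
reconstructionExperiment <- function(model, n_pairs = 500, duration = 100,
                                     seed = 1, spiking_library = NULL,
                                     exc_interval = 10, inh_interval = 10,
                                     dt = 0.025,
                                     library_duration = 100000) {
  stopifnot(is(model, "PointModel"))
  if (n_pairs < 2) stop("n_pairs must be >= 2")
  seeds <- .sub_seeds(seed, n_pairs + 3L)
  if (is.null(spiking_library)) {
    lib_stim <- mergeEvents(
      poissonStream(exc_interval, library_duration, "exc", seeds[1]),
      poissonStream(inh_interval, library_duration, "inh", seeds[2]))
    src <- groundTruthRun(model, lib_stim, library_duration, dt = dt)
    spiking_library <- extractSpikingFrames(src)
  }
  if (length(spiking_library) < 2)
    stop("spiking library must contain at least 2 frames")
  fmat <- frameMatrix(spiking_library)

  acc <- NULL
  pair_idx <- withr::with_seed(seeds[3], replicate(n_pairs, sample.int(
    nrow(fmat), 2, replace = FALSE), simplify = FALSE))
  for (p in seq_len(n_pairs)) {
    stim <- withr::with_seed(seeds[p + 3L], mergeEvents(
      poissonStream(exc_interval, duration, "exc"),
      poissonStream(inh_interval, duration, "inh")))
    fr <- lapply(pair_idx[[p]], function(i) {
      v <- fmat[i, ]
      names(v) <- colnames(fmat)
      v
    })
    tr1 <- simulateModel(model, stim, t_end = duration, dt = dt,
                         init = fr[[1]])
    tr2 <- simulateModel(model, stim, t_end = duration, dt = dt,
                         init = fr[[2]])
    d <- abs(traceVm(tr1) - traceVm(tr2))
    acc <- if (is.null(acc)) d else acc + d
    if (p == 1L) offsets <- traceTimes(tr1)
  }
  structure(list(offsets = offsets, mae = acc / n_pairs,
                 n_pairs = n_pairs, model = model@name, seed = seed),
            class = "onevent_reconstruction")
}

#' Spike-triggered variance and firing-rate summary across models
#'
#' For each model, runs a seeded ground-truth simulation under the
#' default Poisson stimulus and summarizes the spike-triggered Vm
#' variance against baseline, the offsets of peak variance around the
#' spike, and the mean firing rate. Variances are reported for
#' min-max-normalized Vm (the trace is scaled to \[0, 1\] over its
#' observed range), which makes them comparable across models with
#' different spike amplitudes; the percentage-of-baseline column is
#' scale-invariant.
#'
#' @param models character vector of catalogue model names.
#' @param duration ground-truth duration (ms); must yield enough spikes
#'   for stable window statistics.
#' @param seed master seed.
#' @param window spike-centered half-window (ms).
#' @param exc_interval,inh_interval stimulus stream parameters (ms).
#' @param dt integration step (ms).
#' @param min_spikes minimum spike count demanded per model.
#' @return data.frame with one row per model: `model`, `rate_hz`,
#'   `n_spikes`, `baseline_variance`, `min_variance`, `pct_of_baseline`,
#'   `peak_before_ms`, `peak_after_ms`.
#' @export
spikeVarianceSummary <- function(models = listPointModels(),
                                 duration = 100000, seed = 1, window = 20,
                                 exc_interval = 10, inh_interval = 10,
                                 dt = 0.025, min_spikes = 100) {
  seeds <- .sub_seeds(seed, 2L * length(models))
  rows <- lapply(seq_along(models), function(i) {
    m <- pointModel(models[i])
    stim <- mergeEvents(
      poissonStream(exc_interval, duration, "exc", seeds[2 * i - 1]),
      poissonStream(inh_interval, duration, "inh", seeds[2 * i]))
    tr <- groundTruthRun(m, stim, duration, dt = dt)
    if (length(traceSpikes(tr)) < min_spikes)
      stop("insufficient data: model '", models[i], "' produced only ",
           length(traceSpikes(tr)), " spikes in ", duration, " ms")
    stv <- spikeTriggeredVariance(tr, window = window)
    vm_range2 <- diff(range(traceVm(tr)))^2
    data.frame(model = models[i],
               rate_hz = length(traceSpikes(tr)) / duration * 1000,
               n_spikes = length(traceSpikes(tr)),
               baseline_variance = stv$baseline[["vm"]] / vm_range2,
               min_variance = stv$summary$min_vm_variance / vm_range2,
               pct_of_baseline = 100 * stv$summary$min_ratio,
               peak_before_ms = stv$summary$peak_before,
               peak_after_ms = stv$summary$peak_after)
  })
  do.call(rbind, rows)
}
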