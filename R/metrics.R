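# Response-distribution and spike-train metrics: spiking ratio, spike
# prediction coherence, NST dispersion, determinism categories, van
# Rossum distance, ISI histograms, spike matching, spike-triggered
# variance, and transition bookkeeping.

.nsts_of <- function(d) {
  if (is(d, "ResponseDistribution")) d@nsts else as.numeric(d)
}

#' Fraction of spiking responses
#'
#' @param d a [ResponseDistribution-class] (or numeric NST vector with
#'   `Inf` marking non-spiking responses).
#' @return fraction of finite NSTs, in \[0, 1\].
#' @export
spikingRatio <- function(d) {
  nst <- .nsts_of(d)
  if (!length(nst)) stop("empty response distribution")
  mean(is.finite(nst))
}

#' Spike prediction coherence
#'
#' The probability that two responses drawn at random from the
#' distribution agree on spike presence: `r^2 + (1 - r)^2`, where `r` is
#' the spiking ratio. Equals 1 iff all responses agree and attains its
#' minimum 0.5 at `r = 0.5`.
#'
#' @param d a [ResponseDistribution-class] or numeric NST vector.
#' @return coherence in \[0.5, 1\].
#' @export
spikePredictionCoherence <- function(d) {
  r <- spikingRatio(d)
  r^2 + (1 - r)^2
}

#' Standard deviation of spiking next-spike-times
#'
#' Sample standard deviation (denominator k - 1) over the finite NSTs
#' only; infinite (non-spiking) responses do not contribute. With fewer
#' than two finite NSTs the value is undefined and `NA` is returned.
#'
#' @param d a [ResponseDistribution-class] or numeric NST vector.
#' @return standard deviation in ms, or `NA_real_`.
#' @export
nstStd <- function(d) {
  nst <- .nsts_of(d)
  fin <- nst[is.finite(nst)]
  if (length(fin) < 2) return(NA_real_)
  sd(fin)
}

#' Determinism category of a response distribution
#'
#' Classifies by the spiking ratio `r` and NST standard deviation:
#' `DET_NONSPIKING` if `r < 0.01`; with `r >= 0.99`, `DET_SPIKING` if the
#' NST standard deviation is below 0.1 ms and `NONDET_SPIKING` otherwise;
#' and `NONDET` for everything in between. The categories are exhaustive
#' and mutually exclusive. Thresholds are percentages of the response
#' set, so k >= 100 responses are recommended.
#'
#' @param d a [ResponseDistribution-class] or numeric NST vector.
#' @return one of `"DET_NONSPIKING"`, `"DET_SPIKING"`, `"NONDET_SPIKING"`,
#'   `"NONDET"`.
#' @export
classifyResponseSet <- function(d) {
  r <- spikingRatio(d)
  if (r < 0.01) return("DET_NONSPIKING")
  if (r >= 0.99) {
    s <- nstStd(d)
    # a single observed spike time has no measurable jitter
    if (is.na(s) || s < 0.1) return("DET_SPIKING")
    return("NONDET_SPIKING")
  }
  "NONDET"
}

#' van Rossum distance between two spike trains
#'
#' Each train is filtered with the causal exponential kernel
#' `exp(-t/tau)` (for t >= 0) and the distance is
#' `D = sqrt((1/tau) * integral (f_a - f_b)^2 dt)`, evaluated in closed
#' form over spike pairs with no time discretization. Under this
#' normalization a single spike against an empty train gives
#' `sqrt(1/2)`, and two single-spike trains offset by `delta` give
#' `sqrt(1 - exp(-delta/tau))`.
#'
#' @param a,b numeric spike-time vectors (ms), sorted, non-negative.
#' @param tau kernel time constant (ms); conventions for this metric
#'   differ across toolkits, so the value used should always be reported.
#' @return distance >= 0.
#' @examples
#' vanRossumDistance(5, numeric(), tau = 10)  # sqrt(0.5)
#' @export
vanRossumDistance <- function(a, b, tau = 10) {
  if (tau <= 0) stop("tau must be > 0")
  a <- as.numeric(a); b <- as.numeric(b)
  if ((length(a) && min(a) < 0) || (length(b) && min(b) < 0))
    stop("spike times must be non-negative")
  cross <- function(x, y) {
    if (!length(x) || !length(y)) return(0)
    sum(exp(-abs(outer(x, y, "-")) / tau))
  }
  d2 <- 0.5 * (cross(a, a) + cross(b, b) - 2 * cross(a, b))
  sqrt(max(0, d2))
}

#' Inter-spike-interval histogram
#'
#' @param train numeric spike times (ms), sorted.
#' @param bin_width histogram bin width (ms).
#' @return list with `isis` (the N - 1 consecutive differences),
#'   `breaks` and `counts`; all empty for trains with fewer than 2 spikes.
#' @export
isiDistribution <- function(train, bin_width = 1) {
  train <- as.numeric(train)
  if (length(train) < 2)
    return(list(isis = numeric(), breaks = numeric(), counts = integer()))
  isis <- diff(train)
  breaks <- seq(0, (floor(max(isis) / bin_width) + 1) * bin_width,
                by = bin_width)
  counts <- as.integer(table(cut(isis, breaks, right = FALSE,
                                 include.lowest = TRUE)))
  list(isis = isis, breaks = breaks, counts = counts)
}

#' Match predicted spikes against ground truth
#'
#' A predicted spike is matched if any ground-truth spike lies within
#' `tol` ms of it.
#'
#' @param pred,truth sorted numeric spike-time vectors (ms).
#' @param tol matching tolerance (ms).
#' @return list with logical `matched` per predicted spike and counts
#'   `n_matched`, `n_unmatched`.
#' @export
matchSpikes <- function(pred, truth, tol = 1.0) {
  pred <- as.numeric(pred); truth <- as.numeric(truth)
  if (!length(pred))
    return(list(matched = logical(), n_matched = 0L, n_unmatched = 0L))
  if (!length(truth)) {
    m <- rep(FALSE, length(pred))
  } else {
    i <- findInterval(pred, truth)
    lo <- pmax(i, 1L); hi <- pmin(i + 1L, length(truth))
    d <- pmin(abs(pred - truth[lo]), abs(pred - truth[hi]))
    m <- d <= tol
  }
  list(matched = m, n_matched = sum(m), n_unmatched = sum(!m))
}

#' Spike-triggered variance of state variables
#'
#' Aligns fixed windows of the trace at each spike and computes, per time
#' offset from the spike, the variance of each state variable across
#' windows. The baseline is the variance of the variable over the whole
#' trace. Windows overlapping the trace boundary are discarded. The
#' summary reports the minimum spike-centered Vm variance as a fraction
#' of baseline and the offsets of peak Vm variance before and after the
#' spike.
#'
#' @param trace a recorded [Trace-class].
#' @param window half-width of the window (ms); offsets span
#'   `[-window, window]` at the trace step.
#' @param spikes alignment times (ms); defaults to the trace's detected
#'   spikes.
#' @param min_windows minimum number of complete windows required.
#' @return list with `offsets` (ms), `variance` (matrix, offsets x
#'   variables `vm`, `m`, `h`, `n_gate`), `baseline` (named vector),
#'   `n_windows`, and `summary` (`min_vm_variance`, `min_ratio`,
#'   `peak_before`, `peak_after`).
#' @export
spikeTriggeredVariance <- function(trace, window = 20, spikes = NULL,
                                   min_windows = 2) {
  stopifnot(is(trace, "Trace"))
  if (!length(trace@times)) stop("trace was not recorded (record = FALSE)")
  if (is.null(spikes)) spikes <- trace@spike_times
  dt <- trace@dt
  half <- round(window / dt)
  offsets <- seq(-half, half) * dt
  centers <- round((spikes - trace@times[1]) / dt) + 1L
  ok <- centers - half >= 1L & centers + half <= length(trace@times)
  centers <- centers[ok]
  nw <- length(centers)
  if (nw < min_windows)
    stop("insufficient data: only ", nw, " complete spike-centered ",
         "windows (need >= ", min_windows, ")")
  idx <- outer(centers, seq(-half, half), "+")  # nw x n_offsets
  vars <- c("vm", "m", "h", "n_gate")
  col_var <- function(x) {
    w <- matrix(x[idx], nrow = nw)
    (colMeans(w^2) - colMeans(w)^2) * nw / (nw - 1)
  }
  series <- list(vm = trace@vm, m = trace@gates[, "m"],
                 h = trace@gates[, "h"], n_gate = trace@gates[, "n_gate"])
  vmat <- vapply(series, col_var, numeric(length(offsets)))
  baseline <- vapply(series, var, numeric(1))
  vvm <- vmat[, "vm"]
  pre <- offsets < 0; post <- offsets > 0
  summary <- list(
    min_vm_variance = min(vvm),
    min_ratio = if (baseline[["vm"]] > 0) min(vvm) / baseline[["vm"]] else 0,
    peak_before = offsets[pre][which.max(vvm[pre])],
    peak_after = offsets[post][which.max(vvm[post])])
  list(offsets = offsets, variance = vmat, baseline = baseline,
       n_windows = nw, summary = summary)
}

#' Category transitions along growing event windows
#'
#' Given, per stimulus pattern, the determinism category at each
#' consecutive window size n, tallies the category transitions at each
#' n -> n + 1 increment and, for every transition (category change),
#' records features of the newly included stimulus: its inter-stimulus
#' interval to the next more recent event and its label. Unconditional
#' interval and label distributions over all events are returned for
#' comparison.
#'
#' @param categories matrix or data.frame of categories, one row per
#'   pattern, one column per window size; column names are the n values
#'   (consecutive integers).
#' @param histories list of [EventHistory-class] full patterns, parallel
#'   to the rows. Events are ordered oldest to newest; the "n-th most
#'   recent" event is counted from the end.
#' @return list with `tallies` (data.frame `n_from`, `from`, `to`,
#'   `count`), `transitions` (one row per category change: `pattern`,
#'   `n_from`, `from`, `to`, `isi`, `label`), and `unconditional`
#'   (`isis`, `labels` pooled over all histories).
#' @export
transitionAnalysis <- function(categories, histories) {
  categories <- as.matrix(categories)
  n_values <- as.integer(colnames(categories))
  if (any(is.na(n_values)) || (length(n_values) > 1 &&
      any(diff(n_values) != 1L)))
    stop("category columns must be named by consecutive n values")
  if (nrow(categories) != length(histories))
    stop("one history per category row is required")

  tal <- list(); trans <- list()
  for (p in seq_len(nrow(categories))) {
    tt <- eventTimes(histories[[p]])
    ll <- eventLabels(histories[[p]])
    len <- length(tt)
    for (j in seq_len(ncol(categories) - 1)) {
      from <- categories[p, j]; to <- categories[p, j + 1]
      n <- n_values[j]
      tal[[length(tal) + 1L]] <- data.frame(n_from = n, from = from,
                                            to = to)
      if (from != to) {
        new_i <- len - n  # index of the (n+1)-th most recent event
        isi <- if (new_i >= 1 && new_i < len) tt[new_i + 1] - tt[new_i]
               else NA_real_
        lab <- if (new_i >= 1) ll[new_i] else NA_character_
        trans[[length(trans) + 1L]] <- data.frame(
          pattern = p, n_from = n, from = from, to = to,
          isi = isi, label = lab)
      }
    }
  }
  tal <- do.call(rbind, tal)
  tallies <- aggregate(list(count = rep(1L, nrow(tal))),
                       tal[c("n_from", "from", "to")], sum)
  transitions <- if (length(trans)) do.call(rbind, trans) else
    data.frame(pattern = integer(), n_from = integer(),
               from = character(), to = character(), isi = numeric(),
               label = character())
  uncond <- list(
    isis = unlist(lapply(histories, function(h) diff(eventTimes(h)))),
    labels = unlist(lapply(histories, eventLabels)))
  list(tallies = tallies, transitions = transitions,
       unconditional = uncond)
}
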