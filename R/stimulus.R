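# Synthetic stimulus generation: homogeneous Poisson streams and
# fixed-length mixed excitatory/inhibitory patterns.

#' Generate a Poisson stimulus stream
#'
#' Event times follow a homogeneous Poisson process: inter-event
#' intervals are i.i.d. exponential with the given mean. Times are
#' continuous (not grid-snapped); snapping to the integration grid
#' happens only inside the integrator.
#'
#' @param expected_interval mean inter-event interval (ms).
#' @param duration stream duration (ms); events fall in (0, duration].
#' @param label event label, one of `"exc"`, `"inh"`, `"spike"`.
#' @param seed integer seed; the global RNG state is left untouched.
#' @return an [EventHistory-class].
#' @examples
#' poissonStream(40, 1000, "exc", seed = 1)
#' @export
poissonStream <- function(expected_interval, duration, label = "exc",
                          seed = NULL) {
  if (!is.finite(expected_interval) || expected_interval <= 0)
    stop("expected_interval must be > 0")
  if (!is.finite(duration) || duration <= 0)
    stop("duration must be > 0")
  label <- match.arg(label, EVENT_LABELS)
  gen <- function() {
    # draw in chunks until the horizon is passed
    n_guess <- max(10, ceiling(duration / expected_interval * 1.5))
    times <- cumsum(rexp(n_guess, rate = 1 / expected_interval))
    while (length(times) && times[length(times)] < duration) {
      times <- c(times, times[length(times)] +
                   cumsum(rexp(n_guess, rate = 1 / expected_interval)))
    }
    times[times <= duration]
  }
  times <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  eventHistory(times, rep(label, length(times)))
}

#' Generate a fixed-length mixed stimulus pattern
#'
#' Merges an excitatory and an inhibitory Poisson stream, keeps exactly
#' the last `n_events` events, and shifts times so the first kept event
#' is at 0. If the generated streams are too short they are regenerated
#' over a longer duration.
#'
#' @param n_events number of events in the pattern (>= 1).
#' @param exc_interval,inh_interval expected inter-event interval (ms) of
#'   the excitatory and inhibitory stream.
#' @param seed integer seed.
#' @return an [EventHistory-class] of exactly `n_events` events starting
#'   at time 0.
#' @examples
#' makePattern(50, seed = 1)
#' @export
makePattern <- function(n_events, exc_interval = 10, inh_interval = 10,
                        seed = NULL) {
  if (!is.finite(n_events) || n_events < 1)
    stop("n_events must be >= 1")
  rate <- 1 / exc_interval + 1 / inh_interval
  duration <- 1.5 * n_events / rate + 5 / rate
  gen <- function() {
    repeat {
      exc <- poissonStream(exc_interval, duration, "exc")
      inh <- poissonStream(inh_interval, duration, "inh")
      merged <- mergeEvents(exc, inh)
      if (length(merged) >= n_events) return(merged)
      duration <<- duration * 2
    }
  }
  merged <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  patternSuffix(merged, n_events)
}

#' Last-m-events suffix of a pattern, re-anchored at time 0
#'
#' @param history an [EventHistory-class].
#' @param m number of trailing events to keep.
#' @return an [EventHistory-class] of `m` events whose first event is at 0.
#' @export
patternSuffix <- function(history, m) {
  n <- length(history)
  if (m < 1 || m > n) stop("m must be in [1, length(history)]")
  out <- history[(n - m + 1):n]
  eventHistory(eventTimes(out) - eventTimes(out)[1], eventLabels(out))
}
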