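# Fixed-step simulation front end over the compiled integrator.

#' Integrate a point model over an event stream
#'
#' Advances the model with a fixed step: gating variables by the
#' exponential (Rush-Larsen) update, the membrane equation by a
#' trapezoid-consistent update, and synaptic conductances by exact
#' exponential decay. Each synaptic event adds its weight to the matching
#' conductance at the first grid time at or after its timestamp
#' (output-spike events in `events` carry no conductance and are
#' ignored). Output spikes are recorded where the membrane potential
#' crosses 0 mV from below, with sub-step linear interpolation.
#'
#' @param model a [PointModel-class].
#' @param events an [EventHistory-class] of stimuli within `[t0, t_end]`.
#' @param t0,t_end simulation window (ms).
#' @param dt integration step (ms), default 0.025.
#' @param init named initial state frame; default [restingFrame()].
#' @param init_g_exc,init_g_inh initial synaptic conductances (uS).
#' @param record if `FALSE`, only spike times are kept (frames are not
#'   sampled) and the returned trace has empty sample vectors.
#' @return a [Trace-class].
#' @examples
#' m <- pointModel("base")
#' tr <- simulateModel(m, eventHistory(c(5, 7, 9), "exc"), t_end = 50)
#' traceSpikes(tr)
#' @export
simulateModel <- function(model, events = eventHistory(), t0 = 0,
                          t_end = 1000, dt = 0.025, init = NULL,
                          init_g_exc = 0, init_g_inh = 0, record = TRUE) {
  stopifnot(is(model, "PointModel"), is(events, "EventHistory"))
  validObject(model)
  if (dt <= 0) stop("dt must be > 0")
  if (t_end <= t0) stop("empty simulation window: t_end must exceed t0")
  tt <- eventTimes(events)
  ll <- eventLabels(events)
  syn <- ll != "spike"
  tt <- tt[syn]; ll <- ll[syn]
  if (length(tt)) {
    if (is.unsorted(tt)) stop("events must be time-sorted")
    if (min(tt) < t0 || max(tt) > t_end)
      stop("events must lie within [t0, t_end]")
  }
  res <- .cpp_integrate(.model_params(model), .frame_vec(model,
           if (is.null(init)) restingFrame(model) else init),
         init_g_exc, init_g_inh, tt, as.integer(ll == "exc"),
         t0, t_end, dt, record)
  if (record) {
    gates <- cbind(m = res$m, h = res$h, n_gate = res$n_gate)
    new("Trace", times = res$times, vm = res$vm, gates = gates,
        g_exc = res$g_exc, g_inh = res$g_inh, spike_times = res$spikes,
        dt = dt, model = model)
  } else {
    new("Trace", times = numeric(), vm = numeric(),
        gates = matrix(numeric(), 0, 3,
                       dimnames = list(NULL, c("m", "h", "n_gate"))),
        g_exc = numeric(), g_inh = numeric(), spike_times = res$spikes,
        dt = dt, model = model)
  }
}

#' Detect output spikes in a sampled membrane potential
#'
#' A spike is one contiguous upward crossing of 0 mV; its time is
#' linearly interpolated between the bracketing samples. Consecutive
#' spikes are necessarily separated by at least one sub-zero sample.
#'
#' @param vm membrane potential samples (mV).
#' @param times uniform sample times (ms).
#' @return numeric vector of spike times (ms).
#' @examples
#' detectSpikes(c(-10, 10), c(0, 1))  # 0.5
#' @export
detectSpikes <- function(vm, times) {
  if (length(vm) < 2) stop("need at least 2 samples to detect spikes")
  if (length(vm) != length(times)) stop("vm and times lengths differ")
  i <- which(vm[-length(vm)] < 0 & vm[-1] >= 0)
  if (!length(i)) return(numeric())
  times[i] + (times[i + 1] - times[i]) * (0 - vm[i]) / (vm[i + 1] - vm[i])
}
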