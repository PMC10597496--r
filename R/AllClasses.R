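#' Labeled, time-ordered synaptic and output-spike events
#'
#' An `EventHistory` holds a time-ordered sequence of labeled events: the
#' times (ms) of excitatory (`"exc"`) and inhibitory (`"inh"`) synaptic
#' stimuli and, optionally, the cell's own output spikes (`"spike"`).
#' Simultaneous events are kept in the stable order exc < inh < spike so
#' that replay is deterministic.
#'
#' @slot time numeric, event times in ms (non-negative, non-decreasing).
#' @slot label character, one of `"exc"`, `"inh"`, `"spike"` per event.
#'
#' @seealso [eventHistory()], [poissonStream()], [makePattern()]
#' @export
setClass("EventHistory",
  representation(time = "numeric", label = "character"))

setValidity("EventHistory", function(object) {
  msg <- character()
  if (length(object@time) != length(object@label))
    msg <- c(msg, "time and label must have equal length")
  if (length(object@time)) {
    if (any(!is.finite(object@time)) || any(object@time < 0))
      msg <- c(msg, "event times must be finite and >= 0")
    if (is.unsorted(object@time))
      msg <- c(msg, "event times must be non-decreasing")
    if (!all(object@label %in% EVENT_LABELS))
      msg <- c(msg, sprintf("labels must be in {%s}",
                            paste(EVENT_LABELS, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EventHistory
#'
#' Events are sorted by time, with simultaneous events ordered
#' exc < inh < spike.
#'
#' @param time numeric vector of event times (ms).
#' @param label character vector of labels (`"exc"`, `"inh"`, `"spike"`),
#'   recycled if length 1.
#' @return An [EventHistory-class] object.
#' @examples
#' eventHistory(c(0, 5, 5), c("inh", "exc", "inh"))
#' @export
eventHistory <- function(time = numeric(), label = character()) {
  time <- as.numeric(time)
  if (length(label) == 1L && length(time) > 1L)
    label <- rep(label, length(time))
  label <- as.character(label)
  if (length(time)) {
    ord <- order(time, match(label, EVENT_LABELS))
    time <- time[ord]
    label <- label[ord]
  }
  new("EventHistory", time = time, label = label)
}

#' @describeIn EventHistory-class number of events
#' @param x an `EventHistory`.
#' @export
setMethod("length", "EventHistory", function(x) length(x@time))

#' @describeIn EventHistory-class subset, preserving order
#' @param i index vector.
#' @export
setMethod("[", "EventHistory", function(x, i) {
  new("EventHistory", time = x@time[i], label = x@label[i])
})

#' @export
setMethod("show", "EventHistory", function(object) {
  n <- length(object)
  cat(sprintf("EventHistory with %d event%s", n, if (n == 1) "" else "s"))
  if (n) {
    tab <- table(factor(object@label, EVENT_LABELS))
    cat(sprintf(" (%s) spanning [%.6g, %.6g] ms",
                paste(sprintf("%d %s", tab, names(tab)), collapse = ", "),
                object@time[1], object@time[n]))
  }
  cat("\n")
})

#' Event times of an EventHistory
#' @param x an [EventHistory-class].
#' @return numeric vector of times (ms).
#' @export
eventTimes <- function(x) x@time

#' Event labels of an EventHistory
#' @param x an [EventHistory-class].
#' @return character vector of labels.
#' @export
eventLabels <- function(x) x@label

#' Merge two or more event histories
#'
#' @param ... [EventHistory-class] objects.
#' @return a single time-ordered [EventHistory-class].
#' @export
mergeEvents <- function(...) {
  hs <- list(...)
  eventHistory(unlist(lapply(hs, eventTimes)),
               unlist(lapply(hs, eventLabels)))
}

#' Single-compartment conductance-based point model parameterization
#'
#' Bundles the membrane parameters (specific conductances and reversal
#' potentials), compartment geometry, and single-exponential synapse
#' parameters of one model. Conductances are specific (S/cm^2) and are
#' multiplied by the compartment area; synaptic weights are absolute
#' peak-conductance increments (uS) as is conventional for point-process
#' synapses.
#'
#' @slot name model identifier, e.g. `"base"` or `"wb"`.
#' @slot kind `"HH"` or `"WB"`.
#' @slot gna,gk,gl specific conductances (S/cm^2).
#' @slot ena,ek,el reversal potentials (mV).
#' @slot cm specific capacitance (uF/cm^2).
#' @slot area compartment membrane area (cm^2).
#' @slot weight_exc,weight_inh synaptic peak conductance per event (uS).
#' @slot tau_exc,tau_inh synaptic decay time constants (ms).
#' @slot e_exc,e_inh synaptic reversal potentials (mV).
#' @slot phi rate scale for the WB gate kinetics (ignored for HH).
#' @seealso [pointModel()]
#' @export
setClass("PointModel",
  representation(name = "character", kind = "character",
                 gna = "numeric", gk = "numeric", gl = "numeric",
                 ena = "numeric", ek = "numeric", el = "numeric",
                 cm = "numeric", area = "numeric",
                 weight_exc = "numeric", weight_inh = "numeric",
                 tau_exc = "numeric", tau_inh = "numeric",
                 e_exc = "numeric", e_inh = "numeric",
                 phi = "numeric"))

setValidity("PointModel", function(object) {
  msg <- character()
  if (!object@kind %in% c("HH", "WB"))
    msg <- c(msg, "kind must be 'HH' or 'WB'")
  if (any(c(object@gna, object@gk, object@gl) < 0))
    msg <- c(msg, "conductances must be >= 0")
  if (object@area <= 0) msg <- c(msg, "area must be > 0")
  if (object@cm <= 0) msg <- c(msg, "cm must be > 0")
  if (any(c(object@weight_exc, object@weight_inh) < 0))
    msg <- c(msg, "synaptic weights must be >= 0")
  if (any(c(object@tau_exc, object@tau_inh) <= 0))
    msg <- c(msg, "synaptic time constants must be > 0")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "PointModel", function(object) {
  cat(sprintf("PointModel '%s' (%s dynamics)\n", object@name, object@kind))
  cat(sprintf("  membrane: gNa %.4g, gK %.4g, gL %.4g S/cm^2; area %.4g cm^2\n",
              object@gna, object@gk, object@gl, object@area))
  cat(sprintf("  synapses: w_exc %.3g uS (tau %.3g ms), w_inh %.3g uS (tau %.3g ms)\n",
              object@weight_exc, object@tau_exc,
              object@weight_inh, object@tau_inh))
})

#' Sampled trajectory of a point-model simulation
#'
#' A `Trace` records uniformly sampled state variables -- membrane
#' potential, gating variables, synaptic conductances -- plus detected
#' output spike times.
#'
#' @slot times numeric sample times (ms), uniform step.
#' @slot vm membrane potential (mV) per sample.
#' @slot gates matrix of gating variables per sample; columns `m`, `h`,
#'   `n_gate` (for WB, `m` is the instantaneous steady-state value).
#' @slot g_exc,g_inh synaptic conductances (uS) per sample.
#' @slot spike_times detected 0 mV upward crossings (ms, interpolated).
#' @slot dt integration step (ms).
#' @slot model the [PointModel-class] that produced the trace.
#' @export
setClass("Trace",
  representation(times = "numeric", vm = "numeric", gates = "matrix",
                 g_exc = "numeric", g_inh = "numeric",
                 spike_times = "numeric", dt = "numeric",
                 model = "PointModel"))

setValidity("Trace", function(object) {
  msg <- character()
  n <- length(object@times)
  if (length(object@vm) != n || nrow(object@gates) != n)
    msg <- c(msg, "vm and gates must have one entry per sample time")
  if (n >= 2 && is.unsorted(object@times, strictly = TRUE))
    msg <- c(msg, "sample times must be strictly increasing")
  if (length(object@spike_times) && n > 0 &&
      (is.unsorted(object@spike_times, strictly = TRUE) ||
       min(object@spike_times) < object@times[1] ||
       max(object@spike_times) > object@times[n]))
    msg <- c(msg, "spike times must be strictly increasing within the trace")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "Trace", function(object) {
  n <- length(object@times)
  cat(sprintf("Trace of model '%s': %d samples, dt %.4g ms, [%.6g, %.6g] ms, %d spike%s\n",
              object@model@name, n, object@dt, object@times[1],
              object@times[n], length(object@spike_times),
              if (length(object@spike_times) == 1) "" else "s"))
})

#' @describeIn Trace-class number of samples
#' @param x a `Trace`.
#' @export
setMethod("length", "Trace", function(x) length(x@times))

#' Sample times of a Trace
#' @param x a [Trace-class].
#' @export
traceTimes <- function(x) x@times

#' Membrane potential samples of a Trace
#' @param x a [Trace-class].
#' @export
traceVm <- function(x) x@vm

#' Detected spike times of a Trace
#' @param x a [Trace-class].
#' @return numeric vector of spike times (ms).
#' @export
traceSpikes <- function(x) x@spike_times

#' State-variable frame at one sample of a Trace
#'
#' @param x a [Trace-class].
#' @param i sample index.
#' @return named numeric state frame (see [restingFrame()] for the layout).
#' @export
traceFrame <- function(x, i) {
  stopifnot(i >= 1, i <= length(x@times))
  fr <- c(vm = x@vm[i], m = unname(x@gates[i, "m"]),
          h = unname(x@gates[i, "h"]), n_gate = unname(x@gates[i, "n_gate"]))
  if (x@model@kind == "WB") fr <- fr[c("vm", "h", "n_gate")]
  fr
}

#' Library of state-variable initialization frames
#'
#' Frames are snapshots of a model's state variables taken from a long
#' ground-truth run: at random times (`"RANDOM"`), at output-spike onsets
#' (`"SPIKING"`), or the single medoid frame nearest the per-variable
#' medians (`"MEDIAN"`).
#'
#' @slot frames numeric matrix, one frame per row; columns `vm`, `m`, `h`,
#'   `n_gate` for HH models and `vm`, `h`, `n_gate` for WB (whose `m` is
#'   instantaneous and not part of the state).
#' @slot kind `"RANDOM"`, `"SPIKING"` or `"MEDIAN"`.
#' @slot seed integer seed used to draw the frames (`NA` if deterministic).
#' @slot model name of the source model.
#' @export
setClass("FrameLibrary",
  representation(frames = "matrix", kind = "character", seed = "integer",
                 model = "character"))

setValidity("FrameLibrary", function(object) {
  msg <- character()
  if (nrow(object@frames) < 1) msg <- c(msg, "library must be non-empty")
  if (!object@kind %in% c("RANDOM", "SPIKING", "MEDIAN"))
    msg <- c(msg, "kind must be RANDOM, SPIKING or MEDIAN")
  cn <- colnames(object@frames)
  if (is.null(cn) || !"vm" %in% cn)
    msg <- c(msg, "frames must have named columns including 'vm'")
  gate_cols <- setdiff(cn, "vm")
  if (length(gate_cols) && nrow(object@frames)) {
    g <- object@frames[, gate_cols, drop = FALSE]
    if (any(!is.finite(g)) || any(g < 0) || any(g > 1))
      msg <- c(msg, "gating variables must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "FrameLibrary", function(object) {
  cat(sprintf("FrameLibrary (%s) of %d frame%s from model '%s' [%s]\n",
              object@kind, nrow(object@frames),
              if (nrow(object@frames) == 1) "" else "s", object@model,
              paste(colnames(object@frames), collapse = ", ")))
})

#' @describeIn FrameLibrary-class number of frames
#' @param x a `FrameLibrary`.
#' @export
setMethod("length", "FrameLibrary", function(x) nrow(x@frames))

#' Frame matrix of a FrameLibrary
#' @param x a [FrameLibrary-class].
#' @return numeric matrix, one frame per row.
#' @export
frameMatrix <- function(x) x@frames

#' Kind of a FrameLibrary
#' @param x a [FrameLibrary-class].
#' @export
libraryKind <- function(x) x@kind

#' Next-spike-time responses of one stimulus pattern across initializations
#'
#' The multiset of next-spike-times (NSTs) obtained by evaluating an
#' on-event oracle for a single stimulus window from `k` different
#' initialization frames. Non-spiking responses are recorded as `Inf`.
#'
#' @slot nsts numeric NST values in ms; `Inf` marks a non-spiking response.
#' @slot pattern_id identifier of the stimulus pattern.
#' @slot n_window number of events in the input-encoding window.
#' @export
setClass("ResponseDistribution",
  representation(nsts = "numeric", pattern_id = "character",
                 n_window = "integer"))

setValidity("ResponseDistribution", function(object) {
  msg <- character()
  if (length(object@nsts) < 1) msg <- c(msg, "needs at least one response")
  if (any(is.na(object@nsts)) || any(object@nsts <= 0))
    msg <- c(msg, "NSTs must be positive (Inf allowed, NA not)")
  if (length(msg)) msg else TRUE
})

#' Construct a ResponseDistribution
#' @param nsts numeric NSTs (ms; `Inf` = non-spiking response).
#' @param pattern_id pattern identifier.
#' @param n_window window size (number of events).
#' @return a [ResponseDistribution-class].
#' @export
responseDistribution <- function(nsts, pattern_id = "pattern",
                                 n_window = NA_integer_) {
  new("ResponseDistribution", nsts = as.numeric(nsts),
      pattern_id = as.character(pattern_id), n_window = as.integer(n_window))
}

#' @export
setMethod("show", "ResponseDistribution", function(object) {
  r <- spikingRatio(object)
  cat(sprintf("ResponseDistribution '%s' (n = %s): k = %d, spiking ratio %.3f\n",
              object@pattern_id,
              ifelse(is.na(object@n_window), "?", object@n_window),
              length(object@nsts), r))
})

#' NST values of a ResponseDistribution
#' @param x a [ResponseDistribution-class].
#' @export
nstValues <- function(x) x@nsts

#' Number of initializations behind a ResponseDistribution
#' @param x a [ResponseDistribution-class].
#' @export
kResponses <- function(x) length(x@nsts)
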