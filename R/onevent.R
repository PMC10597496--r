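# The on-event discrete-event simulation: a scheduler that invokes an
# on-event function on each stimulus with the n most recent events, and
# the conductance-based oracle that implements the on-event contract by
# re-running the model over the event window.

#' Run an on-event simulation
#'
#' Advances from stimulus to stimulus. On each stimulus the on-event
#' function `fn` receives an [EventHistory-class] of up to `n` recent
#' events (absolute times) whose last entry is the triggering stimulus,
#' and returns the next-spike-time (NST): a strictly positive duration
#' (ms) from the triggering event, or `Inf` for no spike. A predicted
#' spike is committed if it occurs strictly before the next stimulus;
#' otherwise it is discarded and the prediction recomputed (a prediction
#' exactly simultaneous with a stimulus is discarded too). Only one
#' output event can occupy a given time point.
#'
#' With `include_output_spikes = TRUE`, committed output spikes enter the
#' event history (label `"spike"`), and any window containing one is
#' truncated to start at the most recent output spike, since the spike
#' screens off earlier history.
#'
#' During a cold start with fewer than `n` known events, all available
#' events are used.
#'
#' @param stimuli an [EventHistory-class] of synaptic stimuli.
#' @param fn on-event function: `EventHistory -> NST`.
#' @param n window size (number of events, >= 1).
#' @param include_output_spikes logical; feed output spikes back into the
#'   event windows.
#' @param t_end end of simulation (ms); predictions beyond it are
#'   dropped. Defaults to the last stimulus time plus 1000 ms.
#' @return numeric vector of output spike times (ms), strictly increasing.
#' @examples
#' st <- eventHistory(c(0, 10, 20, 30, 40), "exc")
#' runOnEventSim(st, function(w) 1, n = 3)  # 1, 11, 21, 31, 41
#' @export
runOnEventSim <- function(stimuli, fn, n, include_output_spikes = FALSE,
                          t_end = NULL) {
  stopifnot(is(stimuli, "EventHistory"), is.function(fn))
  if (!is.finite(n) || n < 1) stop("window size n must be >= 1")
  st_times <- eventTimes(stimuli)
  st_labels <- eventLabels(stimuli)
  if (any(st_labels == "spike"))
    stop("stimuli must not contain output-spike events")
  if (is.null(t_end))
    t_end <- if (length(st_times)) st_times[length(st_times)] + 1000 else 0

  # growing history of (time, label); spikes appended as committed
  h_time <- numeric(0)
  h_label <- character(0)
  spikes <- numeric(0)
  pending <- NA_real_

  commit <- function(tc) {
    if (length(spikes) && tc <= spikes[length(spikes)]) return(invisible())
    spikes <<- c(spikes, tc)
    if (include_output_spikes) {
      h_time <<- c(h_time, tc)
      h_label <<- c(h_label, "spike")
    }
  }

  for (i in seq_along(st_times)) {
    t_i <- st_times[i]
    if (!is.na(pending) && pending < t_i) {
      commit(pending)
    }
    pending <- NA_real_
    h_time <- c(h_time, t_i)
    h_label <- c(h_label, st_labels[i])

    take <- max(1L, length(h_time) - n + 1L)
    w_time <- h_time[take:length(h_time)]
    w_label <- h_label[take:length(h_label)]
    if (include_output_spikes && any(w_label == "spike")) {
      cut <- max(which(w_label == "spike"))
      w_time <- w_time[cut:length(w_time)]
      w_label <- w_label[cut:length(w_label)]
    }
    nst <- fn(new("EventHistory", time = w_time, label = w_label))
    if (!is.numeric(nst) || length(nst) != 1 || is.na(nst))
      stop("on-event function must return a single numeric NST ",
           "(event at t = ", t_i, " ms)")
    if (nst <= 0)
      stop("on-event function returned NST <= 0 at t = ", t_i, " ms")
    if (is.finite(nst)) pending <- t_i + nst
  }
  if (!is.na(pending) && pending <= t_end) commit(pending)
  spikes[spikes <= t_end]
}

#' Build a conductance-based on-event oracle
#'
#' Returns an on-event function that answers each event window by
#' re-running the conductance-based model itself: (a) a fresh model
#' instance is initialized from a state-variable frame -- a random
#' library frame (`"RANDOM_FRAME"`) or the library medoid
#' (`"MEDIAN_FRAME"`); when the window's first event is an output spike
#' the frame is instead drawn from the spiking library, which pins the
#' model to a spike onset; (b) synaptic conductances start at 0; (c) the
#' window's stimulus events are replayed at their relative times, with
#' the initialization applied at the time of the first window event;
#' (d) the model is integrated for the window span plus `extension` ms;
#' (e) the NST is the time from the last (triggering) event to the first
#' spike strictly after it, or `Inf`. Spikes occurring during replay,
#' before the triggering event, are discarded.
#'
#' @param model a [PointModel-class].
#' @param frames a [FrameLibrary-class] of candidate initializations.
#' @param spiking_frames optional [FrameLibrary-class] of spiking frames,
#'   required to answer windows that start at an output spike.
#' @param mode `"MEDIAN_FRAME"` (deterministic medoid) or
#'   `"RANDOM_FRAME"` (fresh random draw per call).
#' @param extension integration time past the last window event (ms).
#' @param dt integration step (ms).
#' @param seed seed of the oracle's dedicated random-draw stream
#'   (`"RANDOM_FRAME"` mode); the global RNG state is never touched.
#' @return a function `EventHistory -> NST` satisfying the on-event
#'   contract of [runOnEventSim()].
#' @export
conductanceOracle <- function(model, frames, spiking_frames = NULL,
                              mode = c("MEDIAN_FRAME", "RANDOM_FRAME"),
                              extension = 20, dt = 0.025, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(is(model, "PointModel"), is(frames, "FrameLibrary"))
  if (extension <= 0) stop("extension must be > 0")
  params <- .model_params(model)
  fmat <- .frame_matrix4(model, frameMatrix(frames))
  smat <- if (!is.null(spiking_frames))
    .frame_matrix4(model, frameMatrix(spiking_frames)) else NULL
  if (mode == "MEDIAN_FRAME") {
    medoid <- fmat[attr(medianFrame(frames), "index"), , drop = FALSE]
    s_medoid <- if (!is.null(spiking_frames))
      smat[attr(medianFrame(spiking_frames), "index"), , drop = FALSE]
  }
  # dedicated RNG stream for RANDOM_FRAME draws
  rng_state <- withr::with_seed(as.integer(seed), .Random.seed)
  draw <- function(nmax) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    assign(".Random.seed", rng_state, globalenv())
    i <- sample.int(nmax, 1L)
    rng_state <<- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    i
  }

  function(window) {
    stopifnot(is(window, "EventHistory"))
    nw <- length(window)
    if (nw < 1) stop("empty event window")
    w_time <- eventTimes(window)
    w_label <- eventLabels(window)
    rel <- w_time - w_time[1]
    t_last <- rel[nw]

    from_spike <- w_label[1] == "spike"
    if (from_spike && is.null(smat))
      stop("window starts at an output spike but no spiking frame ",
           "library was provided")
    frame <- if (mode == "MEDIAN_FRAME") {
      if (from_spike) s_medoid else medoid
    } else {
      if (from_spike) smat[draw(nrow(smat)), , drop = FALSE]
      else fmat[draw(nrow(fmat)), , drop = FALSE]
    }

    syn <- w_label != "spike"
    .cpp_batch_nst(params, frame, rel[syn],
                   as.integer(w_label[syn] == "exc"),
                   t_last, t_last + extension, dt)[1]
  }
}

#' Ground-truth continuous simulation
#'
#' Convenience wrapper over [simulateModel()] binding the default
#' initialization (rest at -65 mV, steady-state gates, zero synaptic
#' conductance).
#'
#' @param model a [PointModel-class].
#' @param stimuli an [EventHistory-class].
#' @param duration simulation length (ms), from 0.
#' @param dt integration step (ms).
#' @param record record the full state trajectory (see [simulateModel()]).
#' @return a [Trace-class].
#' @export
groundTruthRun <- function(model, stimuli, duration = 10000, dt = 0.025,
                           record = TRUE) {
  if (!is.finite(duration) || duration <= 0)
    stop("duration must be > 0 (empty trace)")
  simulateModel(model, stimuli, t0 = 0, t_end = duration, dt = dt,
                record = record)
}
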