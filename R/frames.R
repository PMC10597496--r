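# State-variable frame libraries: random frames, spiking frames, and the
# medoid ("median") frame of a library.

.trace_frame_matrix <- function(trace, idx) {
  fr <- cbind(vm = trace@vm[idx], m = trace@gates[idx, "m"],
              h = trace@gates[idx, "h"], n_gate = trace@gates[idx, "n_gate"])
  if (trace@model@kind == "WB")
    fr <- fr[, c("vm", "h", "n_gate"), drop = FALSE]
  fr
}

#' Sample random state-variable frames from a trace
#'
#' Draws `k` frames at uniformly random sample times of a recorded
#' ground-truth trace. Such libraries stand in for "unknown initial
#' conditions" when on-event oracles are re-initialized.
#'
#' @param trace a recorded [Trace-class].
#' @param k number of frames.
#' @param seed integer seed; global RNG state is left untouched.
#' @return a [FrameLibrary-class] of kind `"RANDOM"`.
#' @export
sampleRandomFrames <- function(trace, k, seed = NULL) {
  stopifnot(is(trace, "Trace"))
  if (!length(trace@times)) stop("trace was not recorded (record = FALSE)")
  if (!is.finite(k) || k <= 0) stop("k must be a positive count")
  draw <- function() sample.int(length(trace@times), k, replace = TRUE)
  idx <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  new("FrameLibrary", frames = .trace_frame_matrix(trace, idx),
      kind = "RANDOM", seed = if (is.null(seed)) NA_integer_
                              else as.integer(seed),
      model = trace@model@name)
}

#' Extract spiking frames from a trace
#'
#' One frame per detected output spike, sampled at the grid time of the
#' 0 mV upward crossing (the last sub-zero sample), so every frame is an
#' observed state vector with Vm within one integration step of 0 mV.
#'
#' @param trace a recorded [Trace-class] with at least one spike.
#' @return a [FrameLibrary-class] of kind `"SPIKING"`, one frame per spike.
#' @export
extractSpikingFrames <- function(trace) {
  stopifnot(is(trace, "Trace"))
  if (!length(trace@times)) stop("trace was not recorded (record = FALSE)")
  if (!length(trace@spike_times))
    stop("trace contains no spikes; cannot build a spiking frame library")
  idx <- pmax(1L, floor((trace@spike_times - trace@times[1]) / trace@dt) + 1L)
  new("FrameLibrary", frames = .trace_frame_matrix(trace, idx),
      kind = "SPIKING", seed = NA_integer_, model = trace@model@name)
}

#' Medoid frame of a library
#'
#' Computes the per-variable median after min-max normalizing each
#' variable over the library, and returns the observed library member
#' with the minimum Euclidean distance to those medians (never an
#' interpolated frame). Variables that are constant across the library
#' contribute zero to the distance.
#'
#' @param library a [FrameLibrary-class].
#' @return a named numeric state frame, a member of the library, with the
#'   selected row index attached as attribute `"index"`.
#' @export
medianFrame <- function(library) {
  stopifnot(is(library, "FrameLibrary"))
  fr <- library@frames
  rng <- apply(fr, 2, range)
  span <- rng[2, ] - rng[1, ]
  keep <- span > 0
  if (any(keep)) {
    z <- sweep(fr[, keep, drop = FALSE], 2, rng[1, keep], "-")
    z <- sweep(z, 2, span[keep], "/")
    med <- apply(z, 2, median)
    d2 <- rowSums(sweep(z, 2, med, "-")^2)
  } else {
    d2 <- rep(0, nrow(fr))  # all frames identical
  }
  i <- which.min(d2)
  out <- fr[i, ]
  attr(out, "index") <- i
  out
}
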