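# Shared fixtures, built in code and memoized across test files.

.fixture_cache <- new.env(parent = emptyenv())

# A recorded Base ground-truth trace under the default stimulus.
base_trace <- function(duration = 30000, seed = 101) {
  key <- sprintf("base_%d_%d", duration, seed)
  if (is.null(.fixture_cache[[key]])) {
    m <- pointModel("base")
    st <- mergeEvents(poissonStream(10, duration, "exc", seed),
                      poissonStream(10, duration, "inh", seed + 1))
    .fixture_cache[[key]] <- groundTruthRun(m, st, duration)
  }
  .fixture_cache[[key]]
}

# Single-frame library holding one exact frame (used to pin an oracle to
# a known initial state).
frame_library_of <- function(model, frame, kind = "RANDOM") {
  cols <- if (model@kind == "HH") c("vm", "m", "h", "n_gate")
          else c("vm", "h", "n_gate")
  fm <- matrix(frame[cols], 1, length(cols), dimnames = list(NULL, cols))
  new("FrameLibrary", frames = fm, kind = kind, seed = 1L,
      model = model@name)
}

# Hand-built Trace around explicit samples (for metric tests).
synthetic_trace <- function(vm, dt = 0.1, model = pointModel("base"),
                            spikes = numeric()) {
  n <- length(vm)
  new("Trace", times = seq(0, by = dt, length.out = n), vm = vm,
      gates = matrix(0.5, n, 3, dimnames = list(NULL, c("m", "h", "n_gate"))),
      g_exc = numeric(n), g_inh = numeric(n), spike_times = spikes,
      dt = dt, model = model)
}
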