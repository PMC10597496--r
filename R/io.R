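# Text-first file formats and run configuration. All tabular outputs are
# delimited text so results diff cleanly in version control and tests.

#' Read an event file
#'
#' Expects a delimited text file with header `time_ms,label` and labels
#' in `exc`, `inh`, `spike`. Rows must be time-sorted.
#'
#' @param path file path.
#' @return an [EventHistory-class].
#' @export
readEvents <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), c("time_ms", "label")))
    stop("event file must have header 'time_ms,label': ", path)
  if (!nrow(df)) return(eventHistory())
  bad <- which(!df$label %in% EVENT_LABELS)
  if (length(bad))
    stop("invalid label '", df$label[bad[1]], "' at line ", bad[1] + 1L,
         " of ", path)
  bad_t <- which(!is.finite(df$time_ms) | df$time_ms < 0)
  if (length(bad_t))
    stop("invalid time at line ", bad_t[1] + 1L, " of ", path)
  if (is.unsorted(df$time_ms))
    stop("event times are not sorted at line ",
         which(diff(df$time_ms) < 0)[1] + 2L, " of ", path)
  eventHistory(df$time_ms, df$label)
}

#' Write an event file
#'
#' @param history an [EventHistory-class].
#' @param path output path. Full floating precision is preserved, so
#'   `readEvents(writeEvents(h, p))` round-trips losslessly.
#' @export
writeEvents <- function(history, path) {
  stopifnot(is(history, "EventHistory"))
  df <- data.frame(time_ms = format(eventTimes(history), digits = 17,
                                    scientific = FALSE, trim = TRUE),
                   label = eventLabels(history))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spike-train file (one time in ms per line)
#'
#' @param path file path.
#' @return numeric vector of strictly increasing spike times.
#' @export
readSpikeTrain <- function(path) {
  x <- scan(path, what = numeric(), quiet = TRUE)
  if (length(x) >= 2 && any(diff(x) <= 0))
    stop("spike times must be strictly increasing: ", path)
  x
}

#' Write a spike-train file (one time in ms per line)
#'
#' @param train numeric spike times, strictly increasing.
#' @param path output path.
#' @export
writeSpikeTrain <- function(train, path) {
  train <- as.numeric(train)
  if (length(train) >= 2 && any(diff(train) <= 0))
    stop("spike times must be strictly increasing")
  writeLines(format(train, digits = 17, scientific = FALSE, trim = TRUE),
             path)
  invisible(path)
}

#' Write a frame library as delimited text
#'
#' One frame per row, columns named by state variable; kind, seed and
#' source model are stored as `#`-comment header lines.
#'
#' @param library a [FrameLibrary-class].
#' @param path output path.
#' @export
writeFrameLibrary <- function(library, path) {
  stopifnot(is(library, "FrameLibrary"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# kind: ", library@kind),
               paste0("# seed: ", library@seed),
               paste0("# model: ", library@model)), con)
  write.csv(as.data.frame(library@frames), con, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Read a frame library written by [writeFrameLibrary()]
#'
#' @param path file path.
#' @return a [FrameLibrary-class].
#' @export
readFrameLibrary <- function(path) {
  hdr <- readLines(path, n = 3)
  meta <- sub("^# [a-z]+: ", "", hdr)
  df <- read.csv(path, comment.char = "#")
  new("FrameLibrary", frames = as.matrix(df), kind = meta[1],
      seed = suppressWarnings(as.integer(meta[2])), model = meta[3])
}

#' Export a trace as delimited text
#'
#' Columns: `time_ms`, `vm`, `m`, `h`, `n_gate`, `g_exc`, `g_inh`.
#'
#' @param trace a recorded [Trace-class].
#' @param path output path.
#' @export
writeTrace <- function(trace, path) {
  stopifnot(is(trace, "Trace"))
  if (!length(trace@times)) stop("trace was not recorded")
  df <- data.frame(time_ms = trace@times, vm = trace@vm,
                   m = trace@gates[, "m"], h = trace@gates[, "h"],
                   n_gate = trace@gates[, "n_gate"],
                   g_exc = trace@g_exc, g_inh = trace@g_inh)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Run configuration

.config_defaults <- function() {
  list(
    model = "base",
    area = NULL,
    e_exc = 0, e_inh = -75,
    weight_exc = NULL, weight_inh = NULL,
    tau_exc = NULL, tau_inh = NULL,
    dt = 0.025,
    stimulus = list(exc_interval = 10, inh_interval = 10,
                    duration = 10000),
    window = list(n_events = 10, include_output_spikes = FALSE, extension = 20),
    experiment = list(n_patterns = 50, k_frames = 100,
                      n_values = c(3, 5, 10, 15, 25, 50),
                      n_pairs = 500, recon_duration = 100,
                      source_duration = 100000),
    seeds = list(stimulus = 1, frames = 2, patterns = 3, oracle = 4))
}

.check_config <- function(cfg, defaults = .config_defaults(), prefix = "") {
  for (key in names(cfg)) {
    path <- paste0(prefix, key)
    if (!key %in% names(defaults))
      stop("unknown configuration key: ", path)
    if (is.list(defaults[[key]]) && !is.null(cfg[[key]])) {
      if (!is.list(cfg[[key]]))
        stop("configuration key ", path, " must be a mapping")
      .check_config(cfg[[key]], defaults[[key]], paste0(path, "."))
    }
  }
  invisible(TRUE)
}

.merge_config <- function(cfg, defaults) {
  for (key in names(cfg)) {
    if (is.null(cfg[[key]])) next  # explicit null keeps the default
    defaults[[key]] <- if (is.list(defaults[[key]]) && is.list(cfg[[key]]))
      .merge_config(cfg[[key]], defaults[[key]]) else cfg[[key]]
  }
  defaults
}

.validate_config <- function(cfg) {
  if (!cfg$model %in% listPointModels())
    stop("configuration error at key 'model': unknown model '",
         cfg$model, "'")
  for (key in c("tau_exc", "tau_inh"))
    if (!is.null(cfg[[key]]) && cfg[[key]] <= 0)
      stop("configuration error at key '", key, "': must be > 0")
  for (key in c("weight_exc", "weight_inh"))
    if (!is.null(cfg[[key]]) && cfg[[key]] < 0)
      stop("configuration error at key '", key, "': must be >= 0")
  for (key in c("exc_interval", "inh_interval", "duration"))
    if (cfg$stimulus[[key]] <= 0)
      stop("configuration error at key 'stimulus.", key, "': must be > 0")
  if (cfg$window$n_events < 1)
    stop("configuration error at key 'window.n_events': must be >= 1")
  if (cfg$window$extension <= 0)
    stop("configuration error at key 'window.extension': must be > 0")
  if (any(!vapply(cfg$seeds, is.numeric, logical(1))))
    stop("configuration error at key 'seeds': every stochastic ",
         "component needs an integer seed")
  invisible(cfg)
}

#' Load a run configuration
#'
#' Reads a YAML configuration, fills defaults, and validates it. Unknown
#' keys are rejected with the offending key path; every stochastic
#' component must have an explicit seed (defaults are provided).
#'
#' @param path YAML file path.
#' @return validated configuration list (class `"onevent_config"`).
#' @examples
#' p <- tempfile(fileext = ".yaml")
#' writeLines("model: base", p)
#' cfg <- loadRunConfig(p)
#' cfg$stimulus$exc_interval  # default 10 ms
#' @export
loadRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  .check_config(cfg)
  cfg <- .merge_config(cfg, .config_defaults())
  cfg$experiment$n_values <- as.numeric(cfg$experiment$n_values)
  .validate_config(cfg)
  structure(cfg, class = "onevent_config")
}

#' Save a run configuration
#'
#' @param cfg configuration list as returned by [loadRunConfig()].
#' @param path output YAML path. `loadRunConfig(saveRunConfig(cfg, p))`
#'   round-trips to an identical configuration.
#' @export
saveRunConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Construct a model from a run configuration
#'
#' @param cfg configuration list as returned by [loadRunConfig()].
#' @return a [PointModel-class] honouring the configured overrides.
#' @export
modelFromConfig <- function(cfg) {
  pointModel(cfg$model, area = cfg$area, e_exc = cfg$e_exc,
             e_inh = cfg$e_inh, weight_exc = cfg$weight_exc,
             weight_inh = cfg$weight_inh, tau_exc = cfg$tau_exc,
             tau_inh = cfg$tau_inh)
}
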