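#' Spike train
#'
#' A sorted sequence of spike times (ms) for one unit over a trial of known
#' duration.
#'
#' @param times numeric vector of spike times in ms, strictly increasing,
#'   all within `[0, duration]`.
#' @param duration trial duration in ms.
#' @param unit_id identifier of the unit (integer or character).
#' @param unit_type one of `"SAI"`, `"FAI"`, `"cuneate"`.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times, duration, unit_id = 1L,
                        unit_type = c("SAI", "FAI", "cuneate")) {
  unit_type <- match.arg(unit_type)
  times <- as.numeric(times)
  stopifnot_scalar_number(duration, "duration", positive = TRUE)
  if (length(times)) {
    if (any(!is.finite(times))) stop("spike times must be finite", call. = FALSE)
    if (is.unsorted(times, strictly = TRUE)) {
      stop("spike times must be strictly increasing", call. = FALSE)
    }
    if (times[1L] < 0 || times[length(times)] > duration) {
      stop("spike times must lie within [0, duration]", call. = FALSE)
    }
  }
  structure(list(times = times, duration = duration,
                 unit_id = unit_id, unit_type = unit_type),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("spike_train (%s, unit %s): %d spikes over %g ms\n",
              x$unit_type, as.character(x$unit_id), length(x$times),
              x$duration))
  invisible(x)
}

#' @export
length.spike_train <- function(x) length(x$times)

as_spike_times <- function(x) {
  if (inherits(x, "spike_train")) x$times else as.numeric(x)
}

#' Read and write spike trains as JSON
#'
#' A single train is one JSON object `{unit_id, unit_type, duration_ms,
#' times_ms}`; a population is newline-delimited JSON, one object per unit.
#'
#' @param trains a `spike_train` or list of them.
#' @param path file path.
#' @return `read_spike_trains()` returns a list of `spike_train` (possibly
#'   empty); the writer returns `path` invisibly.
#' @export
write_spike_trains <- function(trains, path) {
  if (inherits(trains, "spike_train")) trains <- list(trains)
  lines <- vapply(trains, function(tr) {
    jsonlite::toJSON(list(unit_id = tr$unit_id, unit_type = tr$unit_type,
                          duration_ms = tr$duration,
                          times_ms = as.numeric(format_num(tr$times))),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_spike_trains
#' @export
read_spike_trains <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln)
    spike_train(obj$times_ms, duration = obj$duration_ms,
                unit_id = obj$unit_id, unit_type = obj$unit_type)
  })
}
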