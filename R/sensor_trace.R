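#' Per-taxel sensor drive time series
#'
#' Container for the drive (current/pressure, arbitrary units) of every taxel
#' of the tactile array, sampled uniformly. Rows are taxels in row-major grid
#' order (`r0c0, r0c1, ..., r5c5` for the default 6x6 array), columns are
#' samples.
#'
#' @param data numeric matrix, `rows*cols` x n_samples.
#' @param dt sampling step in ms (> 0).
#' @param rows,cols grid dimensions of the array.
#' @param events named list of event times in ms (e.g. `contact`, `impact`).
#' @return An object of class `sensor_trace`.
#' @export
sensor_trace <- function(data, dt, rows = 6L, cols = 6L, events = list()) {
  data <- unname(as.matrix(data))
  stopifnot_scalar_number(dt, "dt", positive = TRUE)
  if (nrow(data) != rows * cols) {
    stop(sprintf("`data` must have rows*cols = %d rows, got %d",
                 rows * cols, nrow(data)), call. = FALSE)
  }
  if (!is.list(events)) stop("`events` must be a named list", call. = FALSE)
  structure(list(data = data, dt = dt, rows = as.integer(rows),
                 cols = as.integer(cols), events = events),
            class = "sensor_trace")
}

#' @export
print.sensor_trace <- function(x, ...) {
  cat(sprintf("sensor_trace: %dx%d taxels, %d samples at dt=%g ms (%.0f ms)\n",
              x$rows, x$cols, ncol(x$data), x$dt, ncol(x$data) * x$dt))
  if (length(x$events)) {
    cat("  events:", paste(sprintf("%s=%g ms", names(x$events),
                                   unlist(x$events)), collapse = ", "), "\n")
  }
  invisible(x)
}

taxel_labels <- function(rows, cols) {
  idx <- expand.grid(c = seq_len(cols) - 1L, r = seq_len(rows) - 1L)
  sprintf("taxel_r%dc%d", idx$r, idx$c)
}

#' Read and write sensor traces
#'
#' CSV dialect: one header row `time_ms,taxel_r0c0,...,taxel_r5c5`, one row
#' per sample. The JSON dialect additionally stores `dt`, the grid layout and
#' event annotations.
#'
#' @param trace a [sensor_trace()].
#' @param path file path.
#' @param rows,cols grid dimensions assumed when reading CSV.
#' @return `read_sensor_trace_*` return a `sensor_trace`; the writers return
#'   `path` invisibly.
#' @export
write_sensor_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "sensor_trace"))
  tm <- (seq_len(ncol(trace$data)) - 1L) * trace$dt
  df <- data.frame(time_ms = format_num(tm), check.names = FALSE)
  vals <- t(trace$data)
  colnames(vals) <- taxel_labels(trace$rows, trace$cols)
  df <- cbind(df, as.data.frame(apply(vals, 2, format_num)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sensor_trace_csv
#' @export
read_sensor_trace_csv <- function(path, rows = 6L, cols = 6L) {
  df <- read.csv(path, check.names = FALSE)
  expected <- c("time_ms", taxel_labels(rows, cols))
  if (!identical(names(df), expected)) {
    bad <- which(names(df) != expected[seq_along(names(df))])[1]
    stop(sprintf("malformed sensor trace header at column %d: expected '%s'",
                 if (is.na(bad)) length(names(df)) + 1L else bad,
                 expected[if (is.na(bad)) length(names(df)) + 1L else bad]),
         call. = FALSE)
  }
  tm <- df$time_ms
  dt <- if (length(tm) > 1L) median(diff(tm)) else 1
  sensor_trace(t(as.matrix(df[, -1L, drop = FALSE])), dt = dt,
               rows = rows, cols = cols)
}

#' @rdname write_sensor_trace_csv
#' @export
write_sensor_trace_json <- function(trace, path) {
  stopifnot(inherits(trace, "sensor_trace"))
  obj <- list(dt = trace$dt,
              layout = list(rows = trace$rows, cols = trace$cols),
              events = trace$events,
              data = apply(unname(trace$data), 1, function(r)
                as.numeric(format_num(r)), simplify = FALSE))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sensor_trace_csv
#' @export
read_sensor_trace_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  data <- if (is.matrix(obj$data)) obj$data else do.call(rbind, obj$data)
  sensor_trace(data, dt = obj$dt,
               rows = obj$layout$rows, cols = obj$layout$cols,
               events = as.list(obj$events))
}
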