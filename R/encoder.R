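# First-order afferent encoding: porting the sensor current into the
# Izhikevich model and fitting its parameters to reference firing rates.

#' Apply the drive gain to a sensor trace
#'
#' Elementwise gain `K` applied to the per-taxel sensor signal, the porting
#' step between the raw array output and the neuron model input.
#'
#' @param trace a [sensor_trace()], numeric matrix or numeric vector.
#' @param K gain factor, >= 0.
#' @return Same shape as the input: a `sensor_trace` stays a `sensor_trace`.
#' @export
port_sensor_current <- function(trace, K) {
  stopifnot_scalar_number(K, "K", nonneg = TRUE)
  if (inherits(trace, "sensor_trace")) {
    trace$data <- trace$data * K
    trace
  } else {
    trace * K
  }
}

#' Time derivative of a drive series
#'
#' Central differences with one-sided differences at the ends, so the output
#' has the same length as the input. Units are input units per ms. This is
#' the drive pathway of FAI units.
#'
#' @param x numeric vector (one taxel) or matrix (taxels x samples).
#' @param dt sampling step in ms.
#' @return Derivative series, same shape as `x`.
#' @export
drive_derivative <- function(x, dt) {
  stopifnot_scalar_number(dt, "dt", positive = TRUE)
  deriv1 <- function(v) {
    n <- length(v)
    if (n < 2L) stop("drive_derivative needs at least 2 samples", call. = FALSE)
    d <- numeric(n)
    d[1L] <- (v[2L] - v[1L]) / dt
    d[n] <- (v[n] - v[n - 1L]) / dt
    if (n > 2L) d[2:(n - 1L)] <- (v[3:n] - v[1:(n - 2L)]) / (2 * dt)
    d
  }
  if (is.matrix(x)) t(apply(x, 1L, deriv1)) else deriv1(as.numeric(x))
}

#' Simulate first-order afferent spike trains
#'
#' Integrates the Izhikevich model with fixed-step forward Euler under the
#' given drive. SAI (and cuneate) units are driven by `(K/Cm) * drive`; FAI
#' units are driven by `(K/Cm) * dI/dt`, by default rectified so that both
#' stimulus onset and offset excite the unit. A spike is recorded at the
#' first sample where v reaches `v_peak`; the reset (v <- c, u <- u + d)
#' consumes that step, so the recorded v following a spike sample equals `c`
#' exactly.
#'
#' @param drive numeric vector (one unit) or matrix (units x samples) of
#'   sensor drive values sampled at `dt`.
#' @param params an [izh_params()]; `params$unit_type` selects the SAI or
#'   FAI pathway.
#' @param dt integration step in ms (default 0.1). Steps of 1 ms or more
#'   trigger a warning: the quadratic membrane equation is stiff near
#'   threshold.
#' @param signed_deriv if `TRUE`, the FAI pathway uses the signed derivative
#'   instead of its absolute value.
#' @param record_state if `TRUE`, attach the v/u trajectories as attributes
#'   `"v"` and `"u"` (units x samples).
#' @param v0,u0 initial state; defaults to the resting point v = -70 mV,
#'   u = b * v0.
#' @return A `spike_train` for vector drive, or a list of `spike_train` for
#'   matrix drive.
#' @export
simulate_afferent <- function(drive, params = izh_params_sai(), dt = 0.1,
                              signed_deriv = FALSE, record_state = FALSE,
                              v0 = -70, u0 = params$b * v0) {
  stopifnot(inherits(params, "izh_params"))
  stopifnot_scalar_number(dt, "dt", positive = TRUE)
  if (dt >= 1) warning("dt >= 1 ms: Euler integration of the Izhikevich model is unreliable at this step")
  single <- !is.matrix(drive)
  m <- if (single) matrix(as.numeric(drive), nrow = 1L) else drive
  if (any(!is.finite(m))) stop("drive contains non-finite values", call. = FALSE)
  input <- if (params$unit_type == "FAI") {
    d <- drive_derivative(m, dt)
    if (signed_deriv) d else abs(d)
  } else {
    m
  }
  gain <- params$K / params$Cm
  n_units <- nrow(m)
  res <- izh_integrate_cpp(input * gain, dt, params$a, params$b, params$c,
                           params$d, params$v_peak,
                           rep_len(v0, n_units), rep_len(u0, n_units),
                           record_state)
  duration <- ncol(m) * dt
  trains <- lapply(seq_len(n_units), function(j) {
    spike_train(res$spikes[[j]], duration = duration, unit_id = j,
                unit_type = params$unit_type)
  })
  out <- if (single) trains[[1L]] else trains
  attr(out, "final_state") <- list(v = res$v_final, u = res$u_final)
  if (record_state) {
    attr(out, "v") <- res$v
    attr(out, "u") <- res$u
  }
  out
}

#' Goodness of fit between measured and predicted firing rates
#'
#' `FSS = 1 - sum((measured - predicted)^2) / sum(measured^2)`. Equals 1 for
#' an exact prediction and 0 for an all-zero prediction; can be arbitrarily
#' negative.
#'
#' @param measured,predicted equal-length nonempty numeric vectors;
#'   `measured` must not be all zero.
#' @return A scalar in (-Inf, 1].
#' @export
fss <- function(measured, predicted) {
  measured <- as.numeric(measured); predicted <- as.numeric(predicted)
  if (!length(measured) || length(measured) != length(predicted)) {
    stop("`measured` and `predicted` must be nonempty vectors of equal length",
         call. = FALSE)
  }
  denom <- sum(measured^2)
  if (denom == 0) stop("FSS undefined: `measured` is all zero", call. = FALSE)
  1 - sum((measured - predicted)^2) / denom
}

# Predicted steady firing rate (spikes/s) of one parameter set under constant
# drive amplitudes, the forward model used when fitting to reference tables.
predict_rates <- function(params, stimulus, duration_ms = 1000, dt = 0.1) {
  n <- round(duration_ms / dt)
  drive <- matrix(stimulus, nrow = length(stimulus), ncol = n)
  trains <- simulate_afferent(drive, params, dt = dt)
  vapply(trains, function(tr) length(tr$times) / (duration_ms / 1000), numeric(1))
}

#' Fit afferent parameters to a reference stimulus-rate table
#'
#' Maximises the [fss()] goodness of fit between reference firing rates and
#' rates simulated under constant drives, using a deterministic bounded
#' derivative-free search: a coarse grid over the bounded parameters followed
#' by Nelder-Mead refinement (penalised outside the bounds). The returned set
#' never fits worse than `init`.
#'
#' @param reference data frame with columns `stimulus` (constant drive
#'   amplitude, a.u.) and `rate` (spikes/s); at least 3 rows for a
#'   determinate fit. A single row raises an under-determined flag.
#' @param init starting [izh_params()].
#' @param bounds named list of `c(lower, upper)` bounds for the parameters to
#'   optimise over (any of `a`, `b`, `c`, `d`, `K`); defaults to a gain
#'   search `K` in \[5, 120\].
#' @param duration_ms,dt simulation length and step used for predicted rates.
#' @param grid_n grid points per bounded dimension in the coarse stage.
#' @return A list with elements `params` (fitted `izh_params`), `fss`
#'   (achieved goodness of fit), `improved` (logical: beat `init`), and
#'   `underdetermined` (logical flag).
#' @export
fit_afferent_params <- function(reference, init = izh_params_initial(),
                                bounds = list(K = c(5, 120)),
                                duration_ms = 1000, dt = 0.1, grid_n = 9L) {
  if (is.null(dim(reference)) || nrow(reference) == 0L) {
    stop("`reference` must be a nonempty stimulus/rate table", call. = FALSE)
  }
  stopifnot(all(c("stimulus", "rate") %in% names(reference)))
  underdetermined <- nrow(reference) < 3L
  if (underdetermined) {
    warning("fewer than 3 reference points: fit is under-determined")
  }
  if (!length(bounds) || is.null(names(bounds))) {
    stop("`bounds` must be a named list of c(lower, upper)", call. = FALSE)
  }
  par_names <- names(bounds)
  stopifnot(all(par_names %in% c("a", "b", "c", "d", "K")))

  objective <- function(theta) {
    p <- init
    p[par_names] <- as.list(theta)
    # invalid regions get -Inf so the search stays inside the model class
    ok <- p$a > 0 && p$d >= 0 && p$K >= 0 && p$c < p$v_peak
    if (!ok) return(-Inf)
    for (nm in par_names) {
      if (theta[[nm]] < bounds[[nm]][1] || theta[[nm]] > bounds[[nm]][2]) return(-Inf)
    }
    pred <- predict_rates(p, reference$stimulus, duration_ms, dt)
    fss(reference$rate, pred)
  }

  init_theta <- unlist(init[par_names])
  best_theta <- init_theta
  best_val <- objective(init_theta)

  grid_axes <- lapply(bounds, function(b) seq(b[1], b[2], length.out = grid_n))
  grid <- as.matrix(expand.grid(grid_axes))
  for (i in seq_len(nrow(grid))) {
    v <- objective(grid[i, ])
    if (v > best_val) { best_val <- v; best_theta <- grid[i, ] }
  }

  neg_obj <- function(th) {
    v <- objective(stats::setNames(th, par_names))
    if (!is.finite(v)) 1e6 else -v
  }
  refined <- if (length(par_names) == 1L) {
    optim(best_theta, neg_obj, method = "Brent",
          lower = bounds[[1L]][1], upper = bounds[[1L]][2])
  } else {
    optim(best_theta, neg_obj, method = "Nelder-Mead",
          control = list(maxit = 200, reltol = 1e-6))
  }
  ref_val <- objective(stats::setNames(refined$par, par_names))
  if (is.finite(ref_val) && ref_val > best_val) {
    best_val <- ref_val
    best_theta <- refined$par
  }

  out <- init
  out[par_names] <- as.list(stats::setNames(best_theta, par_names))
  improved <- best_val > objective(init_theta) + 1e-12
  if (!improved) {
    # non-improving search: return the initial set, flagged
    out <- init
    best_val <- objective(init_theta)
  }
  list(params = out, fss = best_val, improved = improved,
       underdetermined = underdetermined)
}
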