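# Seeded synthetic stand-ins for the physical rig: taxel drive traces for
# active/reactive grasps of cylinders and spheres, and synergy-structured
# EMG.

#' Define a grasp scenario
#'
#' Describes one touch of a cylinder or sphere by the 6x6 tactile array.
#' The per-taxel plateau amplitude is `(base_amplitude +
#' curvature_gain / diameter_mm) * g`, where `g` is a spatial profile peaked
#' at the array centre: spheres decay radially in both grid axes, cylinders
#' only across the axis. Smaller diameters (larger curvature) therefore give
#' strictly larger drive on every taxel. Reactive scenarios superimpose a
#' damped oscillatory transient plus a brief drive dropout at `impact_time_ms`
#' to mimic a dropped weight and the ensuing slip.
#'
#' @param shape `"cylinder"` or `"sphere"`.
#' @param diameter_mm object diameter in mm, in \[50, 100\].
#' @param mode `"active"` (steady grasp) or `"reactive"` (grasp + impact).
#' @param duration_ms trial duration (default 1000 ms).
#' @param dt sampling step in ms.
#' @param contact_ms contact onset time; the drive ramps up over `ramp_ms`
#'   after it with a raised-cosine edge.
#' @param ramp_ms onset ramp length in ms.
#' @param impact_time_ms impact time for reactive scenarios.
#' @param impact_mass_g mass of the dropped weight in g (default 20); the
#'   transient amplitude scales linearly with it.
#' @param base_amplitude curvature-independent plateau component (a.u.).
#' @param curvature_gain curvature scaling (a.u. * mm); the plateau gains
#'   `curvature_gain / diameter_mm`.
#' @param noise_sd relative trial-to-trial noise: each taxel's amplitude is
#'   jittered by `N(1, noise_sd)` and white noise of sd
#'   `0.5 * noise_sd * amplitude` is added per sample.
#' @param seed integer seed; identical seeds give identical traces.
#' @return An object of class `grasp_scenario`.
#' @export
grasp_scenario <- function(shape = c("cylinder", "sphere"), diameter_mm = 100,
                           mode = c("active", "reactive"), duration_ms = 1000,
                           dt = 0.1, contact_ms = 50, ramp_ms = 100,
                           impact_time_ms = 500, impact_mass_g = 20,
                           base_amplitude = 0.21, curvature_gain = 7,
                           noise_sd = 0.05, seed = 1L) {
  shape <- match.arg(shape)
  mode <- match.arg(mode)
  stopifnot_scalar_number(diameter_mm, "diameter_mm", positive = TRUE)
  stopifnot_scalar_number(duration_ms, "duration_ms", positive = TRUE)
  stopifnot_scalar_number(dt, "dt", positive = TRUE)
  stopifnot_scalar_number(noise_sd, "noise_sd", nonneg = TRUE)
  stopifnot_scalar_number(impact_mass_g, "impact_mass_g", positive = TRUE)
  if (mode == "reactive" && impact_time_ms >= duration_ms) {
    stop("`impact_time_ms` must be before the end of the trial", call. = FALSE)
  }
  structure(list(shape = shape, diameter_mm = diameter_mm, mode = mode,
                 duration_ms = duration_ms, dt = dt, contact_ms = contact_ms,
                 ramp_ms = ramp_ms, impact_time_ms = impact_time_ms,
                 impact_mass_g = impact_mass_g,
                 base_amplitude = base_amplitude,
                 curvature_gain = curvature_gain, noise_sd = noise_sd,
                 seed = seed),
            class = "grasp_scenario")
}

# Spatial sensitivity profile of the 6x6 array: Gaussian fall-off from the
# array centre with a floor, both axes for spheres, across-axis only for
# cylinders. Spheres carry a small amplitude boost (smaller contact patch,
# higher peak pressure).
scenario_profile <- function(shape, rows = 6L, cols = 6L, floor = 0.6,
                             sigma = 1.8) {
  rc <- expand.grid(c = seq_len(cols) - 1L, r = seq_len(rows) - 1L)
  dr <- rc$r - (rows - 1) / 2
  dc <- rc$c - (cols - 1) / 2
  d2 <- if (shape == "sphere") dr^2 + dc^2 else dc^2
  g <- floor + (1 - floor) * exp(-d2 / (2 * sigma^2))
  if (shape == "sphere") g <- g * 1.06
  g
}

#' Generate the sensor trace of a grasp scenario
#'
#' @param scenario a [grasp_scenario()].
#' @return A [sensor_trace()] with `contact` (and for reactive mode
#'   `impact`) event annotations.
#' @export
generate_grasp_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "grasp_scenario"))
  s <- scenario
  n <- round(s$duration_ms / s$dt)
  t <- (seq_len(n) - 1L) * s$dt
  amp0 <- s$base_amplitude + s$curvature_gain / s$diameter_mm
  g <- scenario_profile(s$shape)

  # raised-cosine onset to a constant plateau
  onset <- ifelse(t < s$contact_ms, 0,
                  ifelse(t >= s$contact_ms + s$ramp_ms, 1,
                         0.5 - 0.5 * cos(pi * (t - s$contact_ms) / s$ramp_ms)))

  envelope <- onset
  if (s$mode == "reactive") {
    # damped 50 Hz oscillation settling in ~100 ms, amplitude 3x plateau for
    # the default 20 g weight, plus a brief 70% drive dropout (slip)
    rel <- t - s$impact_time_ms
    active <- rel >= 0
    osc <- numeric(n)
    osc[active] <- 3 * (s$impact_mass_g / 20) *
      exp(-rel[active] / 25) * sin(2 * pi * 0.05 * rel[active])
    drop <- numeric(n)
    drop[active & rel < 30] <- 0.7
    envelope <- onset * (1 - drop) + pmax(osc, 0)
  }

  data <- with_seed(s$seed, {
    jitter <- rnorm(length(g), mean = 1, sd = s$noise_sd)
    base <- outer(amp0 * g * jitter, envelope)
    if (s$noise_sd > 0) {
      base <- base + matrix(rnorm(length(base), sd = 0.5 * s$noise_sd * amp0),
                            nrow = nrow(base))
    }
    base
  })
  data[data < 0] <- 0
  events <- list(contact = s$contact_ms)
  if (s$mode == "reactive") events$impact <- s$impact_time_ms
  sensor_trace(data, dt = s$dt, events = events)
}

#' Simulate one touch end to end
#'
#' Runs a grasp scenario through the full afferent chain: SAI encoding of
#' every taxel, PSP convolution, integration onto the recruited cuneate
#' population, winner-take-all, and the cuneate Izhikevich stage.
#'
#' @param scenario a [grasp_scenario()].
#' @param params afferent parameters (default the SAI-optimised set, since
#'   object discrimination is based on SAI units).
#' @param kernel a [psp_kernel()] sampled at the scenario step.
#' @param map optional precomputed [build_mapping()]; defaults to the map
#'   for the 36-taxel array with `map_seed`.
#' @param gain_cuneate PSP-to-drive scaling of the cuneate stage.
#' @param cuneate_params parameters of the cuneate unit.
#' @param map_seed seed for the default mapping.
#' @return List with `trace`, `afferents` (list of 36 spike trains),
#'   `winner`, `psp_winner`, `cuneate` (the winning unit's spike train) and
#'   `cuneate_rate` (spikes/s over the trial).
#' @export
simulate_touch <- function(scenario, params = izh_params_sai(),
                           kernel = psp_kernel(dt = scenario$dt),
                           map = NULL, gain_cuneate = 0.012,
                           cuneate_params = izh_params_sai("cuneate"),
                           map_seed = 1L) {
  trace <- generate_grasp_scenario(scenario)
  trains <- simulate_afferent(trace$data, params, dt = trace$dt)
  n <- ncol(trace$data)
  psp <- do.call(rbind, lapply(trains, function(tr) {
    convolve_spike_train(tr, kernel, dt = trace$dt)
  }))
  if (is.null(map)) {
    map <- build_mapping(nrow(psp), seed = map_seed)
  }
  total <- integrate_psp(psp, map)
  wta <- winner_take_all(total, dt = trace$dt)
  cuneate <- simulate_cuneate(wta$series, params = cuneate_params,
                              gain = gain_cuneate, dt = trace$dt)
  list(trace = trace, afferents = trains, winner = wta$winner,
       psp_winner = wta$series, cuneate = cuneate,
       cuneate_rate = firing_rate(cuneate))
}

#' Generate synergy-structured raw EMG
#'
#' Each muscle channel is `weight * activation` modulating a band-limited
#' carrier (white noise band-passed to 20-450 Hz), with multiplicative
#' amplitude noise and a small additive noise floor, emulating surface EMG
#' whose envelope has low-rank synergy structure.
#'
#' @param activation activation profile: a numeric vector sampled at `fs`
#'   (one synergy) or a k x n matrix (k synergies).
#' @param weights n_muscles x k nonnegative weight matrix (default: one
#'   synergy over the three long finger/thumb flexors FDP, FDS, FPL).
#' @param noise_fraction relative amplitude noise (default 0.1).
#' @param fs sampling rate in Hz.
#' @param seed integer seed.
#' @param labels channel names.
#' @return List of class `raw_emg`: `signal` (n_muscles x n samples matrix),
#'   `fs`, `labels`.
#' @export
generate_synergy_emg <- function(activation,
                                 weights = matrix(c(1, 0.8, 0.6), ncol = 1),
                                 noise_fraction = 0.1, fs = 1000, seed = 1L,
                                 labels = c("FDP", "FDS", "FPL")) {
  if (is.vector(activation)) activation <- matrix(activation, nrow = 1L)
  weights <- as.matrix(weights)
  if (any(weights < 0) || any(activation < 0)) {
    stop("weights and activations must be nonnegative", call. = FALSE)
  }
  if (ncol(weights) != nrow(activation)) {
    stop("`weights` columns must match `activation` rows", call. = FALSE)
  }
  stopifnot_scalar_number(noise_fraction, "noise_fraction", nonneg = TRUE)
  env <- weights %*% activation        # n_muscles x n
  n_mus <- nrow(env); n <- ncol(env)
  bp <- signal::butter(4, c(20, 450) / (fs / 2), type = "pass")
  sig <- with_seed(seed, {
    out <- matrix(0, n_mus, n)
    for (m in seq_len(n_mus)) {
      carrier <- signal::filtfilt(bp, rnorm(n))
      carrier <- carrier / stats::sd(carrier)
      gain <- env[m, ] * (1 + noise_fraction * rnorm(n))
      floor_amp <- 0.02 * max(env, 1e-12) * noise_fraction / 0.1
      out[m, ] <- gain * carrier + floor_amp * rnorm(n)
    }
    out
  })
  if (length(labels) != n_mus) labels <- paste0("ch", seq_len(n_mus))
  structure(list(signal = sig, fs = fs, labels = labels), class = "raw_emg")
}

#' Default grasp activation profile
#'
#' A smooth rise-hold-release profile used by the synthetic EMG generator:
#' ramp up over `rise_s`, hold, release over `fall_s`.
#'
#' @param duration_s total duration in s.
#' @param fs sampling rate in Hz.
#' @param rise_s,fall_s ramp lengths in s; `fall_s = 0` holds the plateau to
#'   the end of the trial (no release).
#' @param peak plateau level.
#' @return Numeric vector of length `duration_s * fs`.
#' @export
grasp_activation_profile <- function(duration_s = 5, fs = 1000, rise_s = 0.8,
                                     fall_s = 0.8, peak = 1) {
  t <- seq(0, duration_s, length.out = duration_s * fs)
  up <- pmin(1, t / rise_s)
  down <- if (fall_s > 0) pmin(1, pmax(0, (duration_s - t) / fall_s)) else 1
  peak * (0.5 - 0.5 * cos(pi * up)) * (0.5 - 0.5 * cos(pi * down))
}
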