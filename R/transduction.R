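# End-to-end derivation of the sensorimotor transduction function from the
# synthetic study: cuneate firing rate in, muscle-synergy activation out.

#' Resample a binned firing rate onto a uniform grid
#'
#' Linear interpolation of per-bin rates (placed at bin centres) onto a
#' `dt_s` grid, the common time base shared by the tactile input and the
#' EMG-derived activation during system identification.
#'
#' @param binned data frame from [binned_rate()].
#' @param duration_ms trial duration in ms.
#' @param dt_s target sample step in seconds.
#' @return Numeric rate series (spikes/s) of length `duration_ms/1000/dt_s`.
#' @export
resample_rate <- function(binned, duration_ms, dt_s = 0.01) {
  centers <- (binned$bin_start + binned$bin_end) / 2000   # s
  t_out <- seq(0, duration_ms / 1000 - dt_s, by = dt_s)
  approx(centers, binned$rate, xout = t_out, rule = 2)$y
}

#' Derive a transduction controller from the synthetic study
#'
#' Runs the full identification chain on synthetic data: a grasp scenario is
#' encoded to cuneate spikes, whose 200-ms binned rate (resampled to
#' `dt_s`) is the input; synergy-structured EMG generated from a matched
#' activation profile is enveloped and factorised (NMF, one synergy), and
#' the recovered activation - rescaled to peak at `peak_activation` MVC
#' fraction - is the output; a transfer function of the mode's structure
#' (`active`: 2 poles, `reactive`: 3 poles) is then identified between them.
#'
#' For reactive mode the activation profile carries a reflex boost after the
#' impact, so the identified controller raises its output when the cuneate
#' rate transients announce a perturbation.
#'
#' @param mode `"active"` or `"reactive"`.
#' @param seed integer seed for every stochastic stage.
#' @param rate_ref firing rate (spikes/s) mapping to unit model input.
#' @param peak_activation MVC fraction reached at the activation peak.
#' @param duration_ms trial length in ms.
#' @param dt_s identification sample step in seconds.
#' @return A list with `model` (the fitted [tf_model()]), `controller` (a
#'   ready [transduction_controller()]), `rate` (input series), `activation`
#'   (output series) and `synergies` (the NMF decomposition).
#' @export
derive_transduction_controller <- function(mode = c("active", "reactive"),
                                           seed = 1L, rate_ref = 50,
                                           peak_activation = 0.65,
                                           duration_ms = 2000, dt_s = 0.01) {
  mode <- match.arg(mode)
  sc <- grasp_scenario(shape = "sphere", diameter_mm = 70, mode = mode,
                       duration_ms = duration_ms,
                       impact_time_ms = duration_ms / 2,
                       noise_sd = 0.02, seed = derive_seed(seed, 21L))
  touch <- simulate_touch(sc, map_seed = derive_seed(seed, 22L))
  u <- resample_rate(binned_rate(touch$cuneate, 200), duration_ms, dt_s) / rate_ref

  fs <- 1000
  act <- grasp_activation_profile(duration_s = duration_ms / 1000, fs = fs,
                                  rise_s = 0.4, fall_s = 0)
  # activation follows contact: shift the rise to start at the scenario's
  # contact time so the rate -> activation relation stays causal
  shift <- round(sc$contact_ms / 1000 * fs)
  if (shift > 0) act <- c(numeric(shift), act[seq_len(length(act) - shift)])
  if (mode == "reactive") {
    t <- seq_along(act) / fs * 1000
    rel <- t - sc$impact_time_ms
    boost <- ifelse(rel > 0, 0.5 * (1 - exp(-rel / 80)) * exp(-rel / 600), 0)
    act <- pmin(act + boost, 1.5)
  }
  emg <- generate_synergy_emg(act, noise_fraction = 0.1, fs = fs,
                              seed = derive_seed(seed, 23L))
  syn <- extract_synergies(emg_envelope(emg), max_k = 3,
                           seed = derive_seed(seed, 24L), restarts = 5)
  h <- syn$H[1L, ]
  h <- h / max(h) * peak_activation
  t_h <- seq_along(h) / fs
  y <- approx(t_h, h, xout = seq(0, duration_ms / 1000 - dt_s, by = dt_s),
              rule = 2)$y

  # drop the last 200 ms: zero-phase envelope filtering leaves an edge
  # transient there; the window keeps t = 0 so the zero-state simulation of
  # the output-error fit starts where the data do
  trim <- round(0.2 / dt_s)
  keep <- 1L:(length(u) - trim)
  model <- fit_transfer_function(u[keep], y[keep],
                                 structure = if (mode == "active") "active" else "reactive",
                                 dt = dt_s, seed = derive_seed(seed, 25L))
  list(model = model,
       controller = transduction_controller(model, rate_ref = rate_ref),
       rate = u * rate_ref, activation = y, fit_window = keep,
       synergies = syn)
}
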