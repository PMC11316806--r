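# Second-order cuneate layer: PSP convolution of afferent trains, the
# divergence/convergence mapping, winner-take-all selection, and the cuneate
# Izhikevich stage.

#' Postsynaptic potential kernel
#'
#' Causal double-exponential PSP waveform
#' `k(t) = exp(-t/tau_slow) - exp(-t/tau_fast)`, sampled at `dt` over
#' `[0, horizon]`. The kernel is zero at t = 0, nonnegative, has a single
#' interior maximum at `t* = tau_slow*tau_fast/(tau_slow - tau_fast) *
#' log(tau_slow/tau_fast)`, and decays towards zero at the horizon. With the
#' default constants (4 ms and 12.5 ms) the slower exponential is the 12.5 ms
#' one, so it sets the decay of the kernel.
#'
#' @param tau_fast fast time constant in ms (> 0).
#' @param tau_slow slow time constant in ms (> `tau_fast`).
#' @param dt sampling step in ms.
#' @param horizon kernel support in ms; must be at least `5 * tau_slow` so
#'   the tail is negligible.
#' @param normalize if `TRUE` (default) scale the kernel to unit peak.
#' @return An object of class `psp_kernel`: list with `values`, `times`, and
#'   the spec fields.
#' @export
psp_kernel <- function(tau_fast = 4, tau_slow = 12.5, dt = 0.1,
                       horizon = 100, normalize = TRUE) {
  stopifnot_scalar_number(tau_fast, "tau_fast", positive = TRUE)
  stopifnot_scalar_number(tau_slow, "tau_slow", positive = TRUE)
  stopifnot_scalar_number(dt, "dt", positive = TRUE)
  if (tau_fast >= tau_slow) {
    stop("`tau_fast` must be smaller than `tau_slow`", call. = FALSE)
  }
  if (horizon < 5 * tau_slow) {
    stop("`horizon` must be at least 5 * tau_slow", call. = FALSE)
  }
  t <- seq(0, horizon, by = dt)
  v <- exp(-t / tau_slow) - exp(-t / tau_fast)
  if (normalize) v <- v / max(v)
  structure(list(values = v, times = t, tau_fast = tau_fast,
                 tau_slow = tau_slow, dt = dt, horizon = horizon,
                 normalize = normalize),
            class = "psp_kernel")
}

#' Analytic peak time of the PSP kernel
#'
#' @param kernel a [psp_kernel()].
#' @return Peak time in ms.
#' @export
psp_peak_time <- function(kernel) {
  ts <- kernel$tau_slow; tf <- kernel$tau_fast
  ts * tf / (ts - tf) * log(ts / tf)
}

#' Convolve a spike train with a PSP kernel
#'
#' The PSP series equals the superposition of one kernel copy per spike,
#' computed by FFT convolution of the spike indicator series with the
#' sampled kernel.
#'
#' @param train a [spike_train()] (or numeric spike times with `duration`
#'   supplied).
#' @param kernel a [psp_kernel()] sampled at the train's `dt`.
#' @param dt sampling step in ms; must match `kernel$dt`.
#' @param duration series length in ms; defaults to the train's duration.
#' @return Numeric PSP series of length `round(duration/dt)`.
#' @export
convolve_spike_train <- function(train, kernel, dt = kernel$dt,
                                 duration = NULL) {
  stopifnot(inherits(kernel, "psp_kernel"))
  if (abs(dt - kernel$dt) > 1e-12) {
    stop("`dt` must match the kernel sampling step", call. = FALSE)
  }
  times <- as_spike_times(train)
  if (is.null(duration)) {
    if (!inherits(train, "spike_train")) {
      stop("`duration` required when `train` is a bare numeric vector",
           call. = FALSE)
    }
    duration <- train$duration
  }
  n <- round(duration / dt)
  delta <- numeric(n)
  if (length(times)) {
    idx <- pmin(n, round(times / dt) + 1L)
    for (i in idx) delta[i] <- delta[i] + 1
  }
  if (!any(delta != 0)) return(delta)
  out <- convolve(delta, rev(kernel$values), type = "open")
  out[seq_len(n)]
}

#' Number of cuneate neurons recruited by active afferents
#'
#' The smallest integer consistent with the average divergence/convergence
#' ratio of the afferent-to-cuneate projection: each afferent diverges onto
#' `divergence` second-order targets while each cuneate neuron receives at
#' most `convergence` afferent inputs, so `n_active` afferents require at
#' least `ceiling(n_active * divergence / convergence)` cuneate neurons.
#'
#' @param n_active number of active afferents (>= 0).
#' @param divergence,convergence projection ratio (defaults 1700/300).
#' @return Integer count; `recruited_count(100)` is 567.
#' @export
recruited_count <- function(n_active, divergence = 1700, convergence = 300) {
  stopifnot_scalar_number(n_active, "n_active", nonneg = TRUE)
  stopifnot_scalar_number(divergence, "divergence", nonneg = TRUE)
  stopifnot_scalar_number(convergence, "convergence")
  if (convergence <= 0) stop("`convergence` must be > 0", call. = FALSE)
  n_active <- as.integer(round(n_active))
  num <- n_active * as.integer(round(divergence))
  conv <- as.integer(round(convergence))
  as.integer((num + conv - 1L) %/% conv)
}

#' Build the afferent-to-cuneate mapping
#'
#' Recruits `recruited_count(n_afferents)` cuneate neurons and assigns each
#' one a random subset of afferents, sampled uniformly without replacement
#' and capped at `convergence`. When the available afferents do not exceed
#' the convergence cap (the 36-taxel array against a cap of 300), every
#' cuneate neuron connects to all afferents. Edges are excitatory (+1)
#' except for a configurable fraction of inhibitory (-1) edges. The map is
#' reproducible from `seed`.
#'
#' @param n_afferents number of afferent units (>= 1).
#' @param divergence,convergence projection ratio.
#' @param inhibitory_fraction fraction of edges given weight -1 (default 0).
#' @param seed integer seed for the adjacency sampling.
#' @return An object of class `cuneate_map` with `adjacency` and `weights`
#'   lists (one entry per cuneate neuron).
#' @export
build_mapping <- function(n_afferents, divergence = 1700, convergence = 300,
                          inhibitory_fraction = 0, seed = 1L) {
  stopifnot_scalar_number(n_afferents, "n_afferents", positive = TRUE)
  stopifnot_scalar_number(inhibitory_fraction, "inhibitory_fraction", nonneg = TRUE)
  if (inhibitory_fraction > 1) stop("`inhibitory_fraction` must be <= 1", call. = FALSE)
  n_afferents <- as.integer(n_afferents)
  n_cuneate <- recruited_count(n_afferents, divergence, convergence)
  k <- min(n_afferents, as.integer(round(convergence)))
  maps <- with_seed(seed, {
    lapply(seq_len(n_cuneate), function(i) {
      idx <- if (k == n_afferents) seq_len(n_afferents) else
        sort(sample.int(n_afferents, k))
      w <- rep(1, k)
      n_inh <- round(inhibitory_fraction * k)
      if (n_inh > 0) w[sample.int(k, n_inh)] <- -1
      list(idx = idx, w = w)
    })
  })
  structure(list(adjacency = lapply(maps, `[[`, "idx"),
                 weights = lapply(maps, `[[`, "w"),
                 n_afferents = n_afferents, n_cuneate = n_cuneate,
                 divergence = divergence, convergence = convergence,
                 inhibitory_fraction = inhibitory_fraction, seed = seed),
            class = "cuneate_map")
}

#' @export
print.cuneate_map <- function(x, ...) {
  cat(sprintf(
    "cuneate_map: %d afferents -> %d cuneate neurons (ratio %g/%g, inhibitory %g, seed %s)\n",
    x$n_afferents, x$n_cuneate, x$divergence, x$convergence,
    x$inhibitory_fraction, as.character(x$seed)))
  invisible(x)
}

#' Serialize a cuneate mapping to JSON
#'
#' @param map a [build_mapping()] result.
#' @param path file path.
#' @return `read_cuneate_map()` returns a `cuneate_map`; the writer returns
#'   `path` invisibly.
#' @export
write_cuneate_map <- function(map, path) {
  stopifnot(inherits(map, "cuneate_map"))
  jsonlite::write_json(unclass(map), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cuneate_map
#' @export
read_cuneate_map <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  # equal-length per-neuron lists come back simplified to a matrix
  row_list <- function(x, cast) {
    if (is.matrix(x)) {
      lapply(seq_len(nrow(x)), function(i) cast(x[i, ]))
    } else {
      lapply(x, cast)
    }
  }
  structure(list(adjacency = row_list(obj$adjacency, as.integer),
                 weights = row_list(obj$weights, as.numeric),
                 n_afferents = obj$n_afferents, n_cuneate = obj$n_cuneate,
                 divergence = obj$divergence, convergence = obj$convergence,
                 inhibitory_fraction = obj$inhibitory_fraction,
                 seed = obj$seed),
            class = "cuneate_map")
}

#' Integrate afferent PSP series onto the cuneate population
#'
#' For each cuneate neuron, the total postsynaptic potential is the
#' signed-weighted sum of the PSP series of its connected afferents;
#' inhibitory edges subtract.
#'
#' @param psp matrix of per-afferent PSP series (afferents x samples).
#' @param map a [build_mapping()] result for `nrow(psp)` afferents.
#' @return Matrix of per-cuneate PSP_total series (cuneate x samples).
#' @export
integrate_psp <- function(psp, map) {
  stopifnot(inherits(map, "cuneate_map"), is.matrix(psp))
  if (nrow(psp) != map$n_afferents) {
    stop("`psp` must have one row per afferent in the map", call. = FALSE)
  }
  W <- matrix(0, nrow = map$n_cuneate, ncol = map$n_afferents)
  for (i in seq_len(map$n_cuneate)) {
    W[i, map$adjacency[[i]]] <- map$weights[[i]]
  }
  W %*% psp
}

#' Winner-take-all selection over the cuneate population
#'
#' Picks the cuneate neuron with the largest time-integrated PSP_total
#' (trapezoidal integral over the trial). Ties resolve to the lowest index.
#'
#' @param psp_total matrix of per-cuneate PSP series (cuneate x samples), or
#'   a single numeric series.
#' @param dt sampling step in ms.
#' @return List with `winner` (1-based index), `series` (its PSP series) and
#'   `integrals` (all integrals).
#' @export
winner_take_all <- function(psp_total, dt = 0.1) {
  if (!is.matrix(psp_total)) psp_total <- matrix(psp_total, nrow = 1L)
  integrals <- apply(psp_total, 1L, trapz_integral, dt = dt)
  winner <- which.max(integrals)
  list(winner = winner, series = psp_total[winner, ], integrals = integrals)
}

#' Simulate the winning cuneate neuron
#'
#' Feeds `gain * PSP_total` as drive into the Izhikevich model (SAI-type
#' dynamics; the drive is used directly, not differentiated). Parameters
#' default to the SAI-optimised set relabelled as a cuneate unit.
#'
#' @param psp_series numeric PSP_total series of the winning unit.
#' @param params an [izh_params()]; defaults to [izh_params_sai()] with unit
#'   type `"cuneate"`.
#' @param gain scaling from summed PSP to model drive. The default 0.012
#'   places the winning unit of the 36-taxel array in the same tens of
#'   spikes/s regime as the first-order units (see the methods vignette).
#' @param dt integration step in ms.
#' @return A `spike_train` with unit type `"cuneate"`.
#' @export
simulate_cuneate <- function(psp_series, params = izh_params_sai("cuneate"),
                             gain = 0.012, dt = 0.1) {
  stopifnot_scalar_number(gain, "gain", nonneg = TRUE)
  if (params$unit_type == "FAI") {
    stop("cuneate integration uses direct (non-derivative) drive", call. = FALSE)
  }
  simulate_afferent(as.numeric(psp_series) * gain, params, dt = dt)
}
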