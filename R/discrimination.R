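# Object-discrimination protocol under signal detection theory: "noise"
# feature distributions from repeated touches of a baseline object, "signal"
# distributions from touches of the target object, d-prime and hit rates
# over rate-coding and Victor-Purpura features.

#' Define the discrimination protocol
#'
#' Each target object is discriminated from a baseline object of the same
#' shape (default diameter 100 mm); every object is touched
#' `touches_per_object` times.
#'
#' @param shapes object shapes to test.
#' @param diameters_mm object diameters (mm); must contain the baseline.
#' @param baseline_diameter_mm baseline object diameter (default 100).
#' @param touches_per_object touches per object (>= 2, default 10).
#' @param features feature sets to evaluate: `"rate"` (spike count of the
#'   winning cuneate unit over the trial) and/or `"vp"` (Victor-Purpura
#'   distances).
#' @param q Victor-Purpura shift-cost rate (1/ms).
#' @param pairing `"indexed"` pairs each target touch with the same-index
#'   baseline touch (10 signal distances per object pair, 50 per shape);
#'   `"cross"` uses all target x baseline pairs (100 per object pair).
#' @param seed integer seed controlling all touch simulation.
#' @return An object of class `discrimination_protocol`.
#' @export
discrimination_protocol <- function(shapes = c("cylinder", "sphere"),
                                    diameters_mm = c(50, 60, 70, 80, 90, 100),
                                    baseline_diameter_mm = 100,
                                    touches_per_object = 10,
                                    features = c("rate", "vp"), q = 0.05,
                                    pairing = c("indexed", "cross"),
                                    seed = 1L) {
  pairing <- match.arg(pairing)
  shapes <- match.arg(shapes, several.ok = TRUE)
  features <- match.arg(features, several.ok = TRUE)
  if (!baseline_diameter_mm %in% diameters_mm) {
    stop("the baseline diameter must be among `diameters_mm`", call. = FALSE)
  }
  if (touches_per_object < 2) {
    stop("`touches_per_object` must be at least 2", call. = FALSE)
  }
  structure(list(shapes = shapes, diameters_mm = sort(diameters_mm),
                 baseline_diameter_mm = baseline_diameter_mm,
                 touches_per_object = as.integer(touches_per_object),
                 features = features, q = q, pairing = pairing,
                 seed = seed),
            class = "discrimination_protocol")
}

#' Sensitivity index d-prime
#'
#' `(mean(signal) - mean(noise))` divided by the quadratic mean (rms) of the
#' two standard deviations, the unequal-variance form of the index.
#'
#' @param signal_samples,noise_samples numeric vectors with at least 2
#'   samples each.
#' @return d-prime. Errors when the pooled sd is zero.
#' @export
dprime <- function(signal_samples, noise_samples) {
  if (length(signal_samples) < 2L || length(noise_samples) < 2L) {
    stop("need at least 2 samples per distribution", call. = FALSE)
  }
  s1 <- stats::sd(signal_samples); s0 <- stats::sd(noise_samples)
  pooled <- sqrt((s1^2 + s0^2) / 2)
  if (pooled == 0) stop("d-prime undefined: zero pooled sd", call. = FALSE)
  (mean(signal_samples) - mean(noise_samples)) / pooled
}

#' Hit rate of the unbiased observer
#'
#' Percent correct of a yes/no decision with the criterion midway between
#' the two Gaussian means: `Phi(d'/2)`.
#'
#' @param d_prime sensitivity index.
#' @return Proportion in (0, 1).
#' @export
hit_rate_from_dprime <- function(d_prime) {
  pnorm(d_prime / 2)
}

#' Victor-Purpura noise and signal distance sets
#'
#' The "noise" distribution is the set of pairwise VP distances among the
#' baseline touches (`choose(n, 2)` unordered pairs). The "signal"
#' distribution for each target object is, under indexed pairing, one
#' distance per target touch against the same-index baseline touch; under
#' cross pairing, all target x baseline distances.
#'
#' @param trains_by_object named list: each element a list of
#'   `spike_train`s (one per touch) for one object.
#' @param baseline name of the baseline object in `trains_by_object`.
#' @param q VP shift-cost rate (1/ms).
#' @param pairing `"indexed"` or `"cross"`.
#' @return List with `noise` (numeric vector) and `signal` (named list of
#'   numeric vectors, one per non-baseline object).
#' @export
vp_noise_signal_sets <- function(trains_by_object, baseline, q = 0.05,
                                 pairing = c("indexed", "cross")) {
  pairing <- match.arg(pairing)
  stopifnot(baseline %in% names(trains_by_object))
  base <- trains_by_object[[baseline]]
  nb <- length(base)
  noise <- numeric(0)
  if (nb >= 2) {
    pairs <- utils::combn(nb, 2)
    noise <- apply(pairs, 2L, function(ij) {
      vp_distance(base[[ij[1L]]], base[[ij[2L]]], q = q)
    })
  }
  targets <- setdiff(names(trains_by_object), baseline)
  signal <- lapply(targets, function(obj) {
    trs <- trains_by_object[[obj]]
    if (pairing == "indexed") {
      k <- min(length(trs), nb)
      vapply(seq_len(k), function(i) vp_distance(trs[[i]], base[[i]], q = q),
             numeric(1))
    } else {
      as.vector(vapply(seq_along(trs), function(i) {
        vapply(seq_len(nb), function(j) vp_distance(trs[[i]], base[[j]], q = q),
               numeric(1))
      }, numeric(nb)))
    }
  })
  names(signal) <- targets
  list(noise = noise, signal = signal)
}

#' Build the default response source from the synthetic generator
#'
#' Returns a function `(shape, diameter_mm, touch) -> spike_train` that
#' simulates one touch through the full afferent chain ([simulate_touch()])
#' with a per-touch seed derived deterministically from `seed`, and returns
#' the winning cuneate unit's spike train.
#'
#' @param seed integer base seed.
#' @param mode grasp mode passed to the scenario.
#' @param noise_sd trial-to-trial noise of the scenario generator.
#' @param ... further arguments passed to [grasp_scenario()].
#' @return A response-source closure for [run_discrimination_protocol()].
#' @export
touch_response_source <- function(seed = 1L, mode = "active",
                                  noise_sd = 0.05, ...) {
  map <- build_mapping(36L, seed = seed)
  function(shape, diameter_mm, touch) {
    stream <- as.integer(diameter_mm) * 100L + touch +
      ifelse(shape == "sphere", 50000L, 0L)
    sc <- grasp_scenario(shape = shape, diameter_mm = diameter_mm,
                         mode = mode, noise_sd = noise_sd,
                         seed = derive_seed(seed, stream), ...)
    simulate_touch(sc, map = map)$cuneate
  }
}

#' Run the discrimination protocol
#'
#' Simulates (or collects) all touches and produces one row per
#' (shape, non-baseline diameter, feature) with d-prime, the unbiased hit
#' rate and the sample sizes. Degenerate feature distributions (zero pooled
#' sd) yield `NA` with a warning. Provenance (seed, q, pairing) is attached
#' as attributes.
#'
#' @param protocol a [discrimination_protocol()].
#' @param response_source function `(shape, diameter_mm, touch)` returning a
#'   `spike_train`; defaults to the synthetic end-to-end chain seeded from
#'   the protocol.
#' @return Data frame with columns `shape`, `diameter_mm`, `feature`,
#'   `d_prime`, `hit_rate`, `n_signal`, `n_noise`.
#' @export
run_discrimination_protocol <- function(protocol,
                                        response_source =
                                          touch_response_source(protocol$seed)) {
  stopifnot(inherits(protocol, "discrimination_protocol"))
  p <- protocol
  rows <- list()
  for (shape in p$shapes) {
    trains <- list()
    for (d in p$diameters_mm) {
      trains[[as.character(d)]] <- lapply(seq_len(p$touches_per_object),
                                          function(i) response_source(shape, d, i))
    }
    base_key <- as.character(p$baseline_diameter_mm)
    counts <- lapply(trains, function(trs) {
      vapply(trs, function(tr) length(tr$times), numeric(1))
    })
    vp_sets <- if ("vp" %in% p$features) {
      vp_noise_signal_sets(trains, base_key, q = p$q, pairing = p$pairing)
    }
    for (d in setdiff(p$diameters_mm, p$baseline_diameter_mm)) {
      key <- as.character(d)
      if ("rate" %in% p$features) {
        dp <- tryCatch(dprime(counts[[key]], counts[[base_key]]),
                       error = function(e) {
                         warning("degenerate rate distribution for ", shape,
                                 " ", d, " mm: ", conditionMessage(e))
                         NA_real_
                       })
        rows[[length(rows) + 1L]] <- data.frame(
          shape = shape, diameter_mm = d, feature = "rate", d_prime = dp,
          hit_rate = hit_rate_from_dprime(dp),
          n_signal = length(counts[[key]]), n_noise = length(counts[[base_key]]))
      }
      if ("vp" %in% p$features) {
        sig <- vp_sets$signal[[key]]
        dp <- tryCatch(dprime(sig, vp_sets$noise),
                       error = function(e) {
                         warning("degenerate VP distribution for ", shape,
                                 " ", d, " mm: ", conditionMessage(e))
                         NA_real_
                       })
        rows[[length(rows) + 1L]] <- data.frame(
          shape = shape, diameter_mm = d, feature = "vp", d_prime = dp,
          hit_rate = hit_rate_from_dprime(dp),
          n_signal = length(sig), n_noise = length(vp_sets$noise))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "seed") <- p$seed
  attr(out, "q") <- p$q
  attr(out, "pairing") <- p$pairing
  out
}
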