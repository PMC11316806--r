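# Muscle-synergy extraction: EMG envelope preprocessing, multiplicative
# update NMF, variance accounted for, and the synergy-count rule.

#' EMG envelope preprocessing
#'
#' Conventional synergy-analysis pipeline: 4th-order Butterworth band-pass
#' (default 20-450 Hz), full-wave rectification, 4th-order low-pass envelope
#' (default 4 Hz), zero-phase filtering throughout, negatives clipped to
#' zero, and optional unit-maximum normalisation per channel.
#'
#' @param emg a `raw_emg` from [generate_synergy_emg()], or a numeric matrix
#'   (muscles x samples).
#' @param fs sampling rate in Hz (taken from a `raw_emg` input).
#' @param band band-pass edges in Hz.
#' @param lowpass envelope low-pass cutoff in Hz.
#' @param normalize normalise each channel to unit maximum.
#' @param labels channel names.
#' @return An object of class `emg_envelope`: `matrix` (nonnegative,
#'   muscles x samples), `fs`, `labels`.
#' @export
emg_envelope <- function(emg, fs = NULL, band = c(20, 450), lowpass = 4,
                         normalize = TRUE, labels = NULL) {
  if (inherits(emg, "raw_emg")) {
    if (is.null(fs)) fs <- emg$fs
    if (is.null(labels)) labels <- emg$labels
    emg <- emg$signal
  }
  emg <- as.matrix(emg)
  if (is.null(fs)) stop("`fs` required for a bare matrix", call. = FALSE)
  nyq <- fs / 2
  band[2] <- min(band[2], 0.95 * nyq)
  bp <- signal::butter(4, band / nyq, type = "pass")
  lp <- signal::butter(4, lowpass / nyq, type = "low")
  env <- t(apply(emg, 1L, function(ch) {
    if (all(ch == 0)) return(ch)
    e <- signal::filtfilt(lp, abs(signal::filtfilt(bp, ch)))
    pmax(e, 0)
  }))
  if (normalize) {
    mx <- apply(env, 1L, max)
    env <- sweep(env, 1L, ifelse(mx > 0, mx, 1), "/")
  }
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(env)))
  structure(list(matrix = env, fs = fs, labels = labels),
            class = "emg_envelope")
}

env_matrix <- function(V) {
  if (inherits(V, "emg_envelope")) V$matrix else as.matrix(V)
}

#' Nonnegative matrix factorization by multiplicative updates
#'
#' Minimises the squared Frobenius error `||V - WH||^2` with the standard
#' multiplicative updates, whose objective is non-increasing per iteration.
#' The best of `restarts` seeded random initialisations is returned;
#' identical seeds give identical factors.
#'
#' @param V nonnegative matrix (muscles x samples) or an `emg_envelope`.
#' @param k number of synergies (1 <= k <= nrow(V)).
#' @param seed integer seed for the initialisations.
#' @param restarts number of random restarts.
#' @param max_iter maximum iterations per restart.
#' @param tol relative objective tolerance for convergence.
#' @param init optional list `(W, H)` used as one additional initialisation.
#' @return List with `W` (muscles x k), `H` (k x samples), `objective`
#'   (final squared error), `trace` (objective per iteration of the winning
#'   restart) and `iterations`.
#' @export
nmf <- function(V, k, seed = 1L, restarts = 20L, max_iter = 500L,
                tol = 1e-6, init = NULL) {
  V <- env_matrix(V)
  if (any(V < 0)) stop("`V` must be nonnegative", call. = FALSE)
  if (k < 1 || k != round(k)) stop("`k` must be a positive integer", call. = FALSE)
  if (k > nrow(V)) stop("`k` must not exceed the number of muscles", call. = FALSE)
  eps <- .Machine$double.eps
  run_one <- function(W, H) {
    obj <- numeric(0)
    prev <- Inf
    for (it in seq_len(max_iter)) {
      H <- H * (crossprod(W, V)) / (crossprod(W, W %*% H) + eps)
      W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
      e <- sum((V - W %*% H)^2)
      obj <- c(obj, e)
      if (is.finite(prev) && prev - e <= tol * max(prev, eps)) break
      prev <- e
    }
    list(W = W, H = H, objective = e, trace = obj, iterations = length(obj))
  }
  scale0 <- sqrt(mean(V) / k + eps)
  best <- NULL
  with_seed(seed, {
    starts <- lapply(seq_len(restarts), function(r) {
      list(W = matrix(runif(nrow(V) * k), ncol = k) * scale0,
           H = matrix(runif(k * ncol(V)), nrow = k) * scale0)
    })
    if (!is.null(init)) starts <- c(list(init), starts)
    for (st in starts) {
      res <- run_one(st$W, st$H)
      if (is.null(best) || res$objective < best$objective) best <- res
    }
  })
  best
}

#' Variance accounted for
#'
#' Uncentered global VAF of a factorization:
#' `1 - ||V - WH||^2 / ||V||^2`. `per_muscle = TRUE` instead averages the
#' per-channel VAF.
#'
#' @param V nonnegative data matrix or `emg_envelope`.
#' @param W,H factor matrices.
#' @param per_muscle average per-channel VAF instead of the global ratio.
#' @return Fraction (<= 1).
#' @export
vaf <- function(V, W, H, per_muscle = FALSE) {
  V <- env_matrix(V)
  R <- V - W %*% H
  if (per_muscle) {
    mean(1 - rowSums(R^2) / pmax(rowSums(V^2), .Machine$double.eps))
  } else {
    1 - sum(R^2) / sum(V^2)
  }
}

#' Select the synergy count from a VAF curve
#'
#' The smallest k whose VAF exceeds `threshold` with an increment of less
#' than `max_increment` when adding another synergy. If no k below the
#' maximum satisfies the rule, the largest k is returned with the attribute
#' `rule_satisfied = FALSE` and a warning.
#'
#' @param vaf_by_k numeric vector of VAF values for k = 1, 2, ... (names
#'   optional).
#' @param threshold VAF threshold (default 0.85).
#' @param max_increment maximum allowed VAF gain of the next synergy
#'   (default 0.06).
#' @return Integer k with attribute `rule_satisfied`.
#' @export
select_synergy_count <- function(vaf_by_k, threshold = 0.85,
                                 max_increment = 0.06) {
  v <- as.numeric(vaf_by_k)
  k_max <- length(v)
  if (k_max < 1L) stop("`vaf_by_k` must be nonempty", call. = FALSE)
  for (k in seq_len(max(0L, k_max - 1L))) {
    if (v[k] > threshold && (v[k + 1L] - v[k]) < max_increment) {
      return(structure(k, rule_satisfied = TRUE))
    }
  }
  if (k_max >= 1L && v[k_max] > threshold && k_max == 1L) {
    # a single candidate above threshold with nothing to compare against
    return(structure(1L, rule_satisfied = TRUE))
  }
  warning("no synergy count satisfied the VAF rule; returning k_max")
  structure(k_max, rule_satisfied = FALSE)
}

#' Extract muscle synergies from an EMG envelope
#'
#' Runs [nmf()] for k = 1..`max_k`, builds the VAF curve and applies the
#' synergy-count rule. Each k reuses the previous solution (padded with one
#' small extra synergy) as an additional initialisation, which guarantees a
#' non-decreasing VAF curve.
#'
#' @param envelope an `emg_envelope` or nonnegative matrix.
#' @param max_k largest synergy count to consider (default 3, the number of
#'   recorded muscles).
#' @param threshold,max_increment parameters of [select_synergy_count()].
#' @param per_muscle use the per-muscle mean VAF instead of the global VAF.
#' @param seed,restarts,max_iter,tol passed to [nmf()].
#' @return An object of class `synergy_decomposition`: `W`, `H`,
#'   `vaf_by_k`, `selected_k`, `rule_satisfied`, plus the per-k factor list
#'   `fits`.
#' @export
extract_synergies <- function(envelope, max_k = 3L, threshold = 0.85,
                              max_increment = 0.06, per_muscle = FALSE,
                              seed = 1L, restarts = 20L, max_iter = 500L,
                              tol = 1e-6) {
  V <- env_matrix(envelope)
  max_k <- min(max_k, nrow(V))
  fits <- vector("list", max_k)
  vafs <- numeric(max_k)
  prev <- NULL
  for (k in seq_len(max_k)) {
    init <- if (!is.null(prev)) {
      list(W = cbind(prev$W, matrix(mean(prev$W) * 0.01, nrow(V), 1)),
           H = rbind(prev$H, matrix(mean(prev$H) * 0.01, 1, ncol(V))))
    }
    fits[[k]] <- nmf(V, k, seed = derive_seed(seed, k), restarts = restarts,
                     max_iter = max_iter, tol = tol, init = init)
    vafs[k] <- vaf(V, fits[[k]]$W, fits[[k]]$H, per_muscle = per_muscle)
    prev <- fits[[k]]
  }
  sel <- select_synergy_count(vafs, threshold, max_increment)
  structure(list(W = fits[[sel]]$W, H = fits[[sel]]$H,
                 vaf_by_k = vafs, selected_k = as.integer(sel),
                 rule_satisfied = isTRUE(attr(sel, "rule_satisfied")),
                 fits = fits, seed = seed),
            class = "synergy_decomposition")
}

#' @export
print.synergy_decomposition <- function(x, ...) {
  cat(sprintf("synergy_decomposition: selected k = %d (VAF by k: %s)\n",
              x$selected_k,
              paste(sprintf("%.3f", x$vaf_by_k), collapse = ", ")))
  invisible(x)
}
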