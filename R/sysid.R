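# Sensorimotor transduction functions: continuous-time rational transfer
# functions from the second-order tactile signal to the muscle-synergy
# activation, simulated by zero-order-hold discretization and identified by
# output-error minimisation.

#' Continuous-time transfer function model
#'
#' Rational Laplace-domain model `num(S) / den(S)` with coefficients in
#' decreasing powers of S. The two structures used for sensorimotor
#' transduction are `active` (gain over a monic 2nd-order denominator,
#' `a / (S^2 + b S + c)`) and `reactive` (gain over a monic 3rd-order
#' denominator, `a / (S^3 + b S^2 + c S + d)`; printing the denominator
#' monic removes the redundancy of an overall scale).
#'
#' @param num numerator coefficients, decreasing powers of S.
#' @param den denominator coefficients, decreasing powers of S; leading
#'   coefficient must be nonzero. The model must be strictly proper
#'   (`length(num) < length(den)`).
#' @param structure tag: `"active"`, `"reactive"` or `"custom"`.
#' @param fit normalised goodness of fit achieved during identification
#'   (`NA` for hand-built models).
#' @param dt sample step (s) used for discretization during fitting.
#' @return An object of class `tf_model` with a `stable` flag (all poles in
#'   the open left half plane).
#' @export
tf_model <- function(num, den, structure = c("custom", "active", "reactive"),
                     fit = NA_real_, dt = NA_real_) {
  structure_tag <- match.arg(structure)
  num <- as.numeric(num); den <- as.numeric(den)
  if (!length(den) || den[1L] == 0) {
    stop("denominator leading coefficient must be nonzero", call. = FALSE)
  }
  if (length(num) >= length(den)) {
    stop("model must be strictly proper (numerator order < denominator order)",
         call. = FALSE)
  }
  order <- length(den) - 1L
  if (structure_tag == "active" && order != 2L) {
    stop("active structure has 2 poles", call. = FALSE)
  }
  if (structure_tag == "reactive" && order != 3L) {
    stop("reactive structure has 3 poles", call. = FALSE)
  }
  num <- num / den[1L]; den <- den / den[1L]
  poles <- if (order > 0) polyroot(rev(den)) else complex(0)
  structure(list(num = num, den = den, structure = structure_tag,
                 order = order, poles = poles,
                 stable = all(Re(poles) < 0), fit = fit, dt = dt),
            class = "tf_model")
}

#' @export
print.tf_model <- function(x, ...) {
  cat(sprintf("tf_model (%s): order %d, %s, fit=%s\n", x$structure, x$order,
              if (x$stable) "stable" else "UNSTABLE",
              ifelse(is.na(x$fit), "NA", sprintf("%.4f", x$fit))))
  cat("  num:", paste(format_num(x$num), collapse = " "), "\n")
  cat("  den:", paste(format_num(x$den), collapse = " "), "\n")
  invisible(x)
}

# Controllable canonical state space of a strictly proper transfer function.
tf_to_ss <- function(num, den) {
  n <- length(den) - 1L
  a <- den[-1L]                      # a1..an (monic den assumed)
  b <- c(numeric(n - length(num)), num)  # pad numerator to length n
  A <- matrix(0, n, n)
  if (n > 1L) A[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- 1
  A[n, ] <- -rev(a)
  B <- c(numeric(n - 1L), 1)
  C <- rev(b)
  list(A = A, B = B, C = C)
}

# Zero-order-hold discretization to a discrete transfer function (b, a).
tf_discretize <- function(num, den, dt) {
  ss <- tf_to_ss(num, den)
  n <- nrow(ss$A)
  M <- as.matrix(Matrix::expm(rbind(cbind(ss$A, ss$B), 0) * dt))
  Ad <- M[seq_len(n), seq_len(n), drop = FALSE]
  Bd <- M[seq_len(n), n + 1L]
  if (n == 1L) {
    a_z <- c(1, -Ad[1L, 1L])
    b_z <- c(0, Bd[1L] * ss$C[1L])
  } else {
    # charpoly warns when its byproduct inverse is singular; only the
    # coefficients are needed here
    a_z <- suppressWarnings(pracma::charpoly(Ad))
    b_z <- suppressWarnings(pracma::charpoly(Ad - outer(Bd, ss$C))) - a_z
  }
  list(b = b_z, a = a_z)
}

#' Simulate a transfer function model
#'
#' Zero-state response to a sampled input under zero-order-hold
#' discretization (exact for piecewise-constant inputs at the sample
#' points).
#'
#' @param model a [tf_model()].
#' @param u input series.
#' @param dt sample step in seconds.
#' @return Output series of the same length as `u`.
#' @export
tf_simulate <- function(model, u, dt) {
  stopifnot(inherits(model, "tf_model"))
  stopifnot_scalar_number(dt, "dt", positive = TRUE)
  dz <- tf_discretize(model$num, model$den, dt)
  as.numeric(signal::filter(dz$b, dz$a, as.numeric(u)))
}

# Build a monic all-pole candidate from a parameter vector
# theta = c(gain, log(den coefficients a1..an)).
theta_to_model <- function(theta, order, structure = "custom") {
  den <- c(1, exp(theta[-1L]))
  tf_model(theta[1L], den, structure = structure)
}

nrmse_fit <- function(y, yhat) {
  denom <- sqrt(sum((y - mean(y))^2))
  if (denom == 0) return(NA_real_)
  1 - sqrt(sum((y - yhat)^2)) / denom
}

# Least-squares ARX initialisation: discrete AR fit of y on its lags and
# u[t-1], discrete poles mapped to continuous ones through log(z)/dt.
arx_init <- function(u, y, order, dt) {
  n <- length(y)
  default_poles <- -(seq_len(order)) / (n * dt / 10)
  den <- tryCatch({
    lagmat <- sapply(seq_len(order), function(l) y[(order + 1L - l):(n - l)])
    ulag <- u[order:(n - 1L)]
    fitlm <- lm.fit(cbind(lagmat, ulag), y[(order + 1L):n])
    alpha <- fitlm$coefficients[seq_len(order)]
    z <- polyroot(c(-rev(alpha), 1))
    if (any(!is.finite(z)) || any(Mod(z) >= 1) || any(Mod(z) < 1e-8)) {
      stop("unusable ARX poles")
    }
    s <- log(z) / dt
    cden <- Re(pracma::Poly(s))
    if (any(!is.finite(cden)) || any(cden[-1L] <= 0)) stop("non-positive coefficients")
    cden
  }, error = function(e) NULL)
  if (is.null(den)) den <- Re(pracma::Poly(default_poles))
  den <- den / den[1L]
  dc_u <- mean(u)
  gain <- if (abs(dc_u) > 1e-12) mean(y) / dc_u * den[length(den)] else den[length(den)]
  theta <- c(gain, log(pmax(den[-1L], 1e-8)))
  theta[!is.finite(theta)] <- 1
  theta
}

#' Identify a transduction transfer function from input/output data
#'
#' Output-error estimation of an all-pole continuous-time model: the
#' simulated zero-state response is matched to the observed output in the
#' least-squares sense, searching over the gain and the log of the (positive)
#' monic denominator coefficients with seeded multi-start Nelder-Mead, from
#' a discretized ARX least-squares initialisation.
#'
#' @param u input series (e.g. binned cuneate firing rate resampled to the
#'   output rate).
#' @param y output series (muscle-synergy activation), same length as `u`;
#'   at least 10 times the model order in samples.
#' @param structure `"active"` (2 poles), `"reactive"` (3 poles) or an
#'   integer order for a custom all-pole model.
#' @param dt sample step in seconds.
#' @param n_starts number of seeded optimisation starts.
#' @param seed integer seed.
#' @param max_iter Nelder-Mead iteration cap per start.
#' @return A [tf_model()] with its achieved `fit`
#'   (`1 - ||y - yhat|| / ||y - mean(y)||`). A constant input raises an
#'   identifiability warning; an all-zero output returns a zero-gain model
#'   whose fit is `NA` (degenerate).
#' @export
fit_transfer_function <- function(u, y, structure = "active", dt = 0.01,
                                  n_starts = 10L, seed = 1L,
                                  max_iter = 1500L) {
  u <- as.numeric(u); y <- as.numeric(y)
  if (length(u) != length(y)) stop("`u` and `y` must have equal length", call. = FALSE)
  if (is.numeric(structure) && length(structure) == 1L) {
    order <- as.integer(structure); tag <- "custom"
  } else {
    tag <- match.arg(structure, c("active", "reactive"))
    order <- if (tag == "active") 2L else 3L
  }
  if (length(y) < 10L * order) {
    stop("need at least 10 samples per model order", call. = FALSE)
  }
  if (stats::sd(u) == 0) {
    warning("constant input: the system is unexcited and the fit is not identifiable")
  }
  if (all(y == 0)) {
    return(tf_model(0, c(1, rep(1, order)), structure = tag,
                    fit = NA_real_, dt = dt))
  }
  sse <- function(theta) {
    m <- tryCatch(theta_to_model(theta, order), error = function(e) NULL)
    if (is.null(m)) return(1e12)
    yhat <- tryCatch(tf_simulate(m, u, dt), error = function(e) NULL)
    if (is.null(yhat) || any(!is.finite(yhat))) return(1e12)
    v <- sum((y - yhat)^2)
    if (!is.finite(v)) 1e12 else v
  }
  theta0 <- arx_init(u, y, order, dt)
  best <- NULL
  with_seed(seed, {
    for (s in seq_len(n_starts)) {
      th <- if (s == 1L) theta0 else
        theta0 + c(rnorm(1, sd = 0.2 * max(abs(theta0[1L]), 1e-3)),
                   rnorm(order, sd = 0.7))
      opt <- optim(th, sse, method = "Nelder-Mead",
                   control = list(maxit = max_iter, reltol = 1e-10))
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    # polish: restart the simplex from the incumbent until converged
    for (round in 1:3) {
      opt <- optim(best$par, sse, method = "Nelder-Mead",
                   control = list(maxit = max_iter, reltol = 1e-12))
      if (opt$value >= best$value * (1 - 1e-10)) { best <- opt; break }
      best <- opt
    }
  })
  model <- theta_to_model(best$par, order, structure = tag)
  model$fit <- nrmse_fit(y, tf_simulate(model, u, dt))
  model$dt <- dt
  if (!model$stable) warning("identified model is unstable (flagged, not enforced)")
  model
}

#' Select the best transduction structure
#'
#' Fits every candidate structure and returns the one with the largest
#' goodness of fit; fits within `tie_tol` of the best are treated as ties
#' and resolved towards the lowest total order.
#'
#' @param u,y input/output series.
#' @param candidates list of structures accepted by
#'   [fit_transfer_function()] (tags or integer orders).
#' @param dt sample step in seconds.
#' @param tie_tol fit difference below which candidates are tied.
#' @param ... passed to [fit_transfer_function()].
#' @return The winning [tf_model()]; all fitted candidates are attached as
#'   attribute `"candidates"`.
#' @export
select_structure <- function(u, y, candidates = list("active", "reactive"),
                             dt = 0.01, tie_tol = 1e-4, ...) {
  fits <- lapply(candidates, function(st) {
    fit_transfer_function(u, y, structure = st, dt = dt, ...)
  })
  fitvals <- vapply(fits, function(m) ifelse(is.na(m$fit), -Inf, m$fit),
                    numeric(1))
  orders <- vapply(fits, `[[`, integer(1), "order")
  best_fit <- max(fitvals)
  tied <- which(fitvals >= best_fit - tie_tol)
  winner <- tied[which.min(orders[tied])]
  out <- fits[[winner]]
  attr(out, "candidates") <- fits
  out
}

#' Read and write transfer function models as JSON
#'
#' @param model a [tf_model()].
#' @param path file path.
#' @return `read_tf_model()` returns a `tf_model`; the writer returns
#'   `path` invisibly.
#' @export
write_tf_model <- function(model, path) {
  stopifnot(inherits(model, "tf_model"))
  obj <- list(structure = model$structure, num = model$num, den = model$den,
              fit = model$fit, dt = model$dt, stable = model$stable)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tf_model
#' @export
read_tf_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tf_model(obj$num, obj$den, structure = obj$structure,
           fit = if (is.null(obj$fit)) NA_real_ else obj$fit,
           dt = if (is.null(obj$dt)) NA_real_ else obj$dt)
}
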