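#' Izhikevich neuron parameter set
#'
#' Bundles the parameters of the Izhikevich spiking model together with the
#' drive gain used to port sensor currents into the model. The membrane
#' equation is dv/dt = 0.04 v^2 + 5 v + 140 - u + (K/Cm) I(t) with recovery
#' du/dt = a (b v - u) and reset v <- c, u <- u + d whenever v reaches
#' `v_peak` (30 mV).
#'
#' @param a recovery time scale (1/ms); must be > 0.
#' @param b recovery sensitivity (dimensionless).
#' @param c reset potential (mV); must be below `v_peak`.
#' @param d recovery increment at a spike (mV); must be >= 0.
#' @param K drive gain applied to the input signal; must be >= 0.
#' @param Cm capacitance scale (dimensionless). Only the ratio K/Cm is
#'   identifiable from firing rates, so the default folds all gain into K
#'   with Cm = 1.
#' @param v_peak spike cutoff (mV).
#' @param unit_type one of `"SAI"`, `"FAI"`, `"cuneate"`. FAI units are
#'   driven by the time derivative of the input signal.
#' @return An object of class `izh_params`.
#' @seealso [izh_params_sai()], [izh_params_fai()], [izh_params_initial()]
#' @export
izh_params <- function(a = 0.02, b = 0.2, c = -65, d = 6, K = 25, Cm = 1,
                       v_peak = 30, unit_type = c("SAI", "FAI", "cuneate")) {
  unit_type <- match.arg(unit_type)
  stopifnot_scalar_number(a, "a", positive = TRUE)
  stopifnot_scalar_number(b, "b")
  stopifnot_scalar_number(c, "c")
  stopifnot_scalar_number(d, "d", nonneg = TRUE)
  stopifnot_scalar_number(K, "K", nonneg = TRUE)
  stopifnot_scalar_number(Cm, "Cm", positive = TRUE)
  stopifnot_scalar_number(v_peak, "v_peak")
  if (c >= v_peak) stop("reset potential `c` must be below `v_peak`", call. = FALSE)
  structure(list(a = a, b = b, c = c, d = d, K = K, Cm = Cm,
                 v_peak = v_peak, unit_type = unit_type),
            class = "izh_params")
}

#' Reference Izhikevich parameter sets
#'
#' `izh_params_initial()` is the literature starting point used before
#' fitting (a = 0.02, b = 0.2, c = -65, d = 6, K = 25).
#' `izh_params_sai()` and `izh_params_fai()` are the sets optimised against
#' microneurography firing rates for slowly adapting (SAI) and fast adapting
#' (FAI) type I units.
#'
#' @param unit_type label carried by the parameter set; lets the SAI set be
#'   reused for the cuneate stage.
#' @return An `izh_params` object.
#' @export
izh_params_initial <- function(unit_type = "SAI") {
  izh_params(a = 0.02, b = 0.2, c = -65, d = 6, K = 25, unit_type = unit_type)
}

#' @rdname izh_params_initial
#' @export
izh_params_sai <- function(unit_type = "SAI") {
  izh_params(a = 0.02, b = 0.205, c = -65, d = 6.20, K = 55, unit_type = unit_type)
}

#' @rdname izh_params_initial
#' @export
izh_params_fai <- function() {
  izh_params(a = 0.02, b = 0.210, c = -65.5, d = 6.15, K = 56, unit_type = "FAI")
}

#' @export
print.izh_params <- function(x, ...) {
  cat(sprintf("Izhikevich %s unit: a=%g b=%g c=%g d=%g K=%g Cm=%g v_peak=%g\n",
              x$unit_type, x$a, x$b, x$c, x$d, x$K, x$Cm, x$v_peak))
  invisible(x)
}
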