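# Minimal closed-loop grasp plant exercising the transduction-function
# controller: grip command -> contact pressure -> taxel drive -> SAI spikes
# -> cuneate rate -> controller -> next grip command.

#' Define the grasp plant
#'
#' A deliberately simple contact model: the contact pressure (in sensor
#' drive units) is `grip * stiffness - load(t)`, where the load is a small
#' constant plus, in reactive trials, a damped transient at the impact.
#' When the pressure falls below `slip_threshold` the object slips and
#' contact is lost for the rest of the trial. Grip commands act after
#' `motor_delay_ms` and are capped at `max_grip` (100% MVC).
#'
#' @param stiffness pressure per unit grip command.
#' @param baseline_load constant load subtracted from the grip pressure.
#' @param impact_load peak of the impact load transient (for a 20 g weight;
#'   scales with the scenario's `impact_mass_g`).
#' @param impact_decay_ms decay constant of the impact transient.
#' @param slip_threshold pressure below which contact is lost.
#' @param motor_delay_ms actuation delay in ms (default 80).
#' @param max_grip grip command at 100% MVC.
#' @return An object of class `grasp_plant`.
#' @export
grasp_plant <- function(stiffness = 1, baseline_load = 0.05,
                        impact_load = 0.25, impact_decay_ms = 150,
                        slip_threshold = 0.03, motor_delay_ms = 80,
                        max_grip = 1) {
  stopifnot_scalar_number(stiffness, "stiffness", positive = TRUE)
  stopifnot_scalar_number(slip_threshold, "slip_threshold", positive = TRUE)
  stopifnot_scalar_number(motor_delay_ms, "motor_delay_ms", nonneg = TRUE)
  stopifnot_scalar_number(max_grip, "max_grip", positive = TRUE)
  structure(list(stiffness = stiffness, baseline_load = baseline_load,
                 impact_load = impact_load, impact_decay_ms = impact_decay_ms,
                 slip_threshold = slip_threshold,
                 motor_delay_ms = motor_delay_ms, max_grip = max_grip),
            class = "grasp_plant")
}

#' Controllers for the closed loop
#'
#' `constant_controller(level)` holds the grip at a fixed fraction of MVC
#' (`level = 1` is 100% MVC, `level = 0.1` is 10% MVC).
#' `transduction_controller(model, rate_ref, out_gain)` drives the grip with
#' the transduction function's response to the normalised cuneate firing
#' rate: `grip = out_gain * activation`, clipped to `[0, max_grip]`, where
#' `activation` is the model output for input `rate / rate_ref`.
#'
#' @param level constant MVC fraction.
#' @param model a [tf_model()].
#' @param rate_ref firing rate (spikes/s) mapping to unit model input.
#' @param out_gain grip command per unit activation.
#' @return A controller object for [run_closed_loop()].
#' @export
constant_controller <- function(level) {
  stopifnot_scalar_number(level, "level", nonneg = TRUE)
  structure(list(type = "constant", level = level), class = "grasp_controller")
}

#' @rdname constant_controller
#' @export
transduction_controller <- function(model, rate_ref = 50, out_gain = 1) {
  stopifnot(inherits(model, "tf_model"))
  stopifnot_scalar_number(rate_ref, "rate_ref", positive = TRUE)
  structure(list(type = "tf", model = model, rate_ref = rate_ref,
                 out_gain = out_gain), class = "grasp_controller")
}

#' Run the closed-loop grasp simulation
#'
#' Steps the plant at `control_dt_ms` (default 10 ms). Each step: the
#' current grip and scenario load set the contact pressure; the pressure
#' drives the taxel array (spatial profile of the scenario's shape); SAI
#' afferents are integrated incrementally and their PSPs summed into the
#' cuneate unit, whose firing rate over the trailing 200 ms window is the
#' controller input; the controller output becomes the grip command applied
#' after the motor delay. A slip (pressure below threshold) ends contact:
#' pressure and drive drop to zero and no further spikes occur.
#'
#' @param controller a [constant_controller()] or
#'   [transduction_controller()].
#' @param plant a [grasp_plant()].
#' @param scenario a [grasp_scenario()]; `mode = "reactive"` adds the
#'   impact load transient at `impact_time_ms`.
#' @param params afferent parameters (SAI set by default).
#' @param gain_cuneate,cuneate_params cuneate stage configuration.
#' @param control_dt_ms control step in ms.
#' @param rate_window_ms firing-rate window for the controller input.
#' @param initial_grip starting grip command (fraction of `max_grip`).
#' @param seed integer seed for the sensor noise.
#' @return A data frame log with columns `time_ms`, `pressure`, `grip_cmd`,
#'   `cuneate_rate`, `slip_flag`, with the scenario and seeds attached as
#'   attributes.
#' @export
run_closed_loop <- function(controller, plant = grasp_plant(),
                            scenario = grasp_scenario(mode = "reactive"),
                            params = izh_params_sai(),
                            gain_cuneate = 0.012,
                            cuneate_params = izh_params_sai("cuneate"),
                            control_dt_ms = 10, rate_window_ms = 200,
                            initial_grip = 0.5, seed = 1L) {
  if (!inherits(controller, "grasp_controller")) {
    stop("a controller is required (constant_controller or transduction_controller)",
         call. = FALSE)
  }
  stopifnot(inherits(plant, "grasp_plant"), inherits(scenario, "grasp_scenario"))
  s <- scenario
  dt <- s$dt
  sub <- round(control_dt_ms / dt)        # integration samples per control step
  n_steps <- round(s$duration_ms / control_dt_ms)
  profile <- scenario_profile(s$shape)
  n_tax <- length(profile)
  kernel <- psp_kernel(dt = dt)

  # incremental afferent/cuneate state
  v_a <- rep(-70, n_tax); u_a <- params$b * v_a
  v_c <- -70; u_c <- cuneate_params$b * v_c
  # PSP as two exponential accumulators per afferent (difference form of the
  # double-exponential kernel, scaled to unit peak like psp_kernel)
  peak <- max(exp(-kernel$times / kernel$tau_slow) -
                exp(-kernel$times / kernel$tau_fast))
  e_slow <- numeric(n_tax); e_fast <- numeric(n_tax)
  dec_s <- exp(-dt / kernel$tau_slow); dec_f <- exp(-dt / kernel$tau_fast)

  delay_steps <- max(0L, round(plant$motor_delay_ms / control_dt_ms))
  cmd_queue <- rep(initial_grip, delay_steps + 1L)
  grip <- initial_grip
  contact <- TRUE
  spike_times <- numeric(0)

  # controller state (discretized transduction function at the control step)
  tf_state <- NULL
  if (controller$type == "tf") {
    ss <- tf_to_ss(controller$model$num, controller$model$den)
    M <- as.matrix(Matrix::expm(rbind(cbind(ss$A, ss$B), 0) *
                                  (control_dt_ms / 1000)))
    nn <- nrow(ss$A)
    Ad <- M[seq_len(nn), seq_len(nn), drop = FALSE]
    Bd <- M[seq_len(nn), nn + 1L]
    # start from the tonic-grasp equilibrium (unit normalised rate input) so
    # the loop does not transiently release an already-established grasp
    x0 <- tryCatch(solve(diag(nn) - Ad, Bd),
                   error = function(e) numeric(nn))
    tf_state <- list(Ad = Ad, Bd = Bd, C = ss$C, x = x0)
  }

  noise <- with_seed(derive_seed(seed, 1L), {
    matrix(rnorm(n_tax * sub * n_steps, sd = 0.5 * s$noise_sd * 0.3),
           nrow = n_tax)
  })

  log <- data.frame(time_ms = numeric(n_steps), pressure = numeric(n_steps),
                    grip_cmd = numeric(n_steps),
                    cuneate_rate = numeric(n_steps),
                    slip_flag = logical(n_steps))
  for (step in seq_len(n_steps)) {
    t_ms <- (step - 1L) * control_dt_ms
    # plant: pressure under current grip and scenario load
    load <- plant$baseline_load
    if (s$mode == "reactive" && t_ms >= s$impact_time_ms) {
      load <- load + plant$impact_load * (s$impact_mass_g / 20) *
        exp(-(t_ms - s$impact_time_ms) / plant$impact_decay_ms)
    }
    pressure <- grip * plant$stiffness - load
    if (contact && pressure < plant$slip_threshold) {
      contact <- FALSE
    }
    if (!contact) pressure <- 0
    pressure <- max(pressure, 0)

    # sense: taxel drive over this control step
    cols <- ((step - 1L) * sub + 1L):(step * sub)
    drive <- outer(profile * pressure, rep(1, sub)) + noise[, cols, drop = FALSE]
    drive[drive < 0] <- 0
    res <- izh_integrate_cpp(drive * (params$K / params$Cm), dt,
                             params$a, params$b, params$c, params$d,
                             params$v_peak, v_a, u_a, FALSE)
    v_a <- res$v_final; u_a <- res$u_final

    # PSP accumulators advanced sample by sample, spikes injected at their
    # sample, then cuneate integration over the step
    psp_step <- matrix(0, 1L, sub)
    inc <- matrix(0, n_tax, sub)
    for (j in seq_len(n_tax)) {
      idx <- pmin(sub, round(res$spikes[[j]] / dt) + 1L)
      for (i in idx) inc[j, i] <- inc[j, i] + 1
    }
    for (i in seq_len(sub)) {
      e_slow <- e_slow * dec_s + inc[, i]
      e_fast <- e_fast * dec_f + inc[, i]
      psp_step[1L, i] <- sum(e_slow - e_fast) / peak
    }
    resc <- izh_integrate_cpp(psp_step * gain_cuneate *
                                (cuneate_params$K / cuneate_params$Cm), dt,
                              cuneate_params$a, cuneate_params$b,
                              cuneate_params$c, cuneate_params$d,
                              cuneate_params$v_peak, v_c, u_c, FALSE)
    v_c <- resc$v_final; u_c <- resc$u_final
    if (length(resc$spikes[[1L]])) {
      spike_times <- c(spike_times, t_ms + resc$spikes[[1L]])
    }
    win0 <- max(0, t_ms + control_dt_ms - rate_window_ms)
    rate <- sum(spike_times >= win0) /
      ((t_ms + control_dt_ms - win0) / 1000)

    # act: controller output enters the delay queue
    cmd <- if (controller$type == "constant") {
      controller$level * plant$max_grip
    } else {
      tf_state$x <- as.vector(tf_state$Ad %*% tf_state$x +
                                tf_state$Bd * (rate / controller$rate_ref))
      min(max(controller$out_gain * sum(tf_state$C * tf_state$x), 0),
          plant$max_grip)
    }
    cmd_queue <- c(cmd_queue, min(cmd, plant$max_grip))
    grip <- cmd_queue[1L]
    cmd_queue <- cmd_queue[-1L]

    log$time_ms[step] <- t_ms
    log$pressure[step] <- pressure
    log$grip_cmd[step] <- grip
    log$cuneate_rate[step] <- rate
    log$slip_flag[step] <- !contact
  }
  attr(log, "scenario") <- scenario
  attr(log, "seed") <- seed
  attr(log, "controller_type") <- controller$type
  log
}
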