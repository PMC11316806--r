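# Independent reference implementations used to cross-check the package.
# These deliberately share no code with the implementations under test: the
# Euler oracle is a plain scalar R loop, the VP oracle enumerates monotone
# matchings recursively, the convolution oracle shifts and adds.

# Scalar forward-Euler integration of the Izhikevich model; same reset
# convention as the package (spike sample consumes the step), but written
# independently and usable at arbitrary step sizes.
oracle_izh_spikes <- function(drive_fun, params, dt, duration_ms,
                              v0 = -70, u0 = params$b * v0) {
  n <- round(duration_ms / dt)
  v <- v0; u <- u0
  spikes <- numeric(0)
  gain <- params$K / params$Cm
  for (i in seq_len(n)) {
    t <- (i - 1) * dt
    if (v >= params$v_peak) {
      spikes <- c(spikes, t)
      v <- params$c
      u <- u + params$d
    } else {
      dv <- 0.04 * v^2 + 5 * v + 140 - u + gain * drive_fun(t)
      du <- params$a * (params$b * v - u)
      v <- v + dt * dv
      u <- u + dt * du
    }
  }
  spikes
}

# Exhaustive Victor-Purpura distance: minimum over all monotone pairings of
# spikes between the two trains.
oracle_vp <- function(a, b, q) {
  rec <- function(i, j) {
    if (i > length(a)) return(length(b) - j + 1)
    if (j > length(b)) return(length(a) - i + 1)
    min(1 + rec(i + 1, j),
        1 + rec(i, j + 1),
        q * abs(a[i] - b[j]) + rec(i + 1, j + 1))
  }
  rec(1, 1)
}

# Shift-and-add superposition of kernel copies at each spike time.
oracle_convolve <- function(times, kernel_values, dt, n) {
  out <- numeric(n)
  for (tk in times) {
    i0 <- round(tk / dt)
    len <- min(length(kernel_values), n - i0)
    if (len > 0) {
      idx <- (i0 + 1):(i0 + len)
      out[idx] <- out[idx] + kernel_values[seq_len(len)]
    }
  }
  out
}

# Random sorted spike train over [0, duration].
random_train <- function(n, duration = 1000) {
  sort(runif(n, 0, duration))
}

# Analytic ZOH step response of a / (s^2 + b s + c) with distinct real
# poles -p1, -p2 (p1 != p2): exact at the sample points.
oracle_step_response_2p <- function(a, p1, p2, t) {
  (a / (p1 * p2)) * (1 - (p2 * exp(-p1 * t) - p1 * exp(-p2 * t)) / (p2 - p1))
}
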