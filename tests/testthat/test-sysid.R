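# Transfer-function simulation and output-error identification.

test_that("tf_model validates structure and normalises the denominator", {
  m <- tf_model(4, c(2, 4, 6), structure = "active")
  expect_equal(m$den, c(1, 2, 3))
  expect_equal(m$num, 2)
  expect_true(m$stable)
  expect_error(tf_model(c(1, 1, 1), c(1, 2, 3)), "strictly proper")
  expect_error(tf_model(1, c(0, 1, 2)), "nonzero")
  expect_error(tf_model(1, c(1, 2), structure = "active"), "2 poles")
  unstable <- tf_model(1, c(1, -3, 2))
  expect_false(unstable$stable)
})

test_that("tf_simulate matches analytic responses", {
  # a / (S^2 + bS + c) with poles -2 and -5
  a <- 30; p1 <- 2; p2 <- 5
  m <- tf_model(a, c(1, p1 + p2, p1 * p2), structure = "active")
  dt <- 0.001
  n <- 6000
  expect_equal(tf_simulate(m, rep(0, n), dt), rep(0, n))
  y <- tf_simulate(m, rep(1, n), dt)
  # final value theorem: steady state a/c; t = 6 s is 12 slow time constants
  expect_lt(abs(y[n] - a / (p1 * p2)) / (a / (p1 * p2)), 0.01)
  # ZOH response to a piecewise-constant input is exact at the samples
  # sample k of the output is time (k-1)*dt; ZOH is exact at the samples
  t <- (seq_len(n) - 1) * dt
  expect_lt(max(abs(y - oracle_step_response_2p(a, p1, p2, t))), 1e-6)
  # pulse of width dt: difference of two shifted step responses
  u_pulse <- c(1 / dt, rep(0, n - 1))
  y_pulse <- tf_simulate(m, u_pulse, dt)
  closed <- (oracle_step_response_2p(a, p1, p2, t + dt) -
               oracle_step_response_2p(a, p1, p2, pmax(t, 0))) / dt
  expect_lt(max(abs(y_pulse[-1] - closed[-n])) / max(abs(closed)), 1e-6)
})

test_that("tf_simulate is linear and consistent under step refinement", {
  m <- tf_model(10, c(1, 3, 8), structure = "active")
  set.seed(61)
  u <- cumsum(rnorm(400)) / 10
  y1 <- tf_simulate(m, u, 0.01)
  y2 <- tf_simulate(m, 3.7 * u, 0.01)
  expect_equal(y2, 3.7 * y1, tolerance = 1e-9)
  # halving dt changes the step response by < 0.5%
  # sample k of the coarse run is time (k-1)*dt, i.e. fine sample 2k-1
  ya <- tf_simulate(m, rep(1, 1000), 0.01)
  yb <- tf_simulate(m, rep(1, 2000), 0.005)
  expect_lt(max(abs(ya - yb[seq(1, 1999, 2)])) / max(abs(ya)), 0.005)
})

sim_with_noise <- function(m, u, dt, frac, seed) {
  y <- tf_simulate(m, u, dt)
  set.seed(seed)
  y + rnorm(length(y), sd = frac * sd(y))
}

test_that("known active and reactive models are recovered within 5%", {
  dt <- 0.01
  set.seed(62)
  u <- as.numeric(stats::filter(pmax(rnorm(600), 0), rep(0.2, 5),
                                sides = 1))
  u[is.na(u)] <- 0
  truth_a <- tf_model(40, c(1, 6, 25), structure = "active")
  y <- sim_with_noise(truth_a, u, dt, 0.01, 101)
  fit_a <- fit_transfer_function(u, y, "active", dt = dt, seed = 1)
  expect_lt(max(abs(fit_a$num - truth_a$num) / abs(truth_a$num),
                abs(fit_a$den[-1] - truth_a$den[-1]) / abs(truth_a$den[-1])),
            0.05)
  expect_gt(fit_a$fit, 0.95)
  truth_r <- tf_model(60, c(1, 9, 35, 50), structure = "reactive")
  yr <- sim_with_noise(truth_r, u, dt, 0.01, 102)
  fit_r <- fit_transfer_function(u, yr, "reactive", dt = dt, seed = 1)
  expect_lt(max(abs(fit_r$num - truth_r$num) / abs(truth_r$num),
                abs(fit_r$den[-1] - truth_r$den[-1]) / abs(truth_r$den[-1])),
            0.05)
})

test_that("degenerate identification inputs are flagged", {
  dt <- 0.01
  expect_warning(fit_transfer_function(rep(1, 100), rnorm(100), "active",
                                       dt = dt, n_starts = 2, max_iter = 20),
                 "unexcited")
  m0 <- fit_transfer_function(runif(100), rep(0, 100), "active", dt = dt)
  expect_equal(m0$num, 0)
  expect_true(is.na(m0$fit))
  expect_error(fit_transfer_function(runif(15), runif(15), "reactive",
                                     dt = dt), "10 samples per")
})

test_that("structure selection prefers the true order", {
  dt <- 0.01
  set.seed(63)
  u <- as.numeric(stats::filter(pmax(rnorm(500), 0), rep(0.2, 5), sides = 1))
  u[is.na(u)] <- 0
  truth <- tf_model(40, c(1, 6, 25), structure = "active")
  y <- tf_simulate(truth, u, dt)
  best <- select_structure(u, y, candidates = list(1L, "active", "reactive"),
                           dt = dt, n_starts = 4, max_iter = 250, seed = 2)
  expect_equal(best$order, 2L)
  truth3 <- tf_model(60, c(1, 9, 35, 50), structure = "reactive")
  y3 <- tf_simulate(truth3, u, dt)
  best3 <- select_structure(u, y3, candidates = list(1L, "active", "reactive"),
                            dt = dt, n_starts = 4, max_iter = 250, seed = 2)
  expect_equal(best3$order, 3L)
})

test_that("recovery degrades gracefully with noise", {
  dt <- 0.01
  set.seed(64)
  u <- as.numeric(stats::filter(pmax(rnorm(500), 0), rep(0.2, 5), sides = 1))
  u[is.na(u)] <- 0
  truth <- tf_model(40, c(1, 6, 25), structure = "active")
  errs <- vapply(c(0, 0.01, 0.05, 0.10), function(frac) {
    y <- sim_with_noise(truth, u, dt, frac, 200 + round(frac * 100))
    f <- fit_transfer_function(u, y, "active", dt = dt, seed = 3,
                               n_starts = 4, max_iter = 250)
    mean(abs(c(f$num, f$den[-1]) - c(truth$num, truth$den[-1])) /
           abs(c(truth$num, truth$den[-1])))
  }, numeric(1))
  expect_gt(cor(seq_along(errs), errs, method = "spearman"), 0.5)
  expect_lt(errs[1], errs[4])
})

test_that("tf models serialize losslessly", {
  m <- tf_model(40, c(1, 6, 25), structure = "active", fit = 0.93, dt = 0.01)
  path <- tempfile(fileext = ".json")
  write_tf_model(m, path)
  m2 <- read_tf_model(path)
  expect_equal(m$num, m2$num)
  expect_equal(m$den, m2$den)
  expect_equal(m$structure, m2$structure)
  expect_equal(m$fit, m2$fit)
})
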