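# Synthetic grasp scenarios, synergy EMG and end-to-end monotonicity.

test_that("scenario plateaus scale with curvature on every taxel", {
  tr50 <- generate_grasp_scenario(grasp_scenario("cylinder", 50, noise_sd = 0,
                                                 seed = 1))
  tr100 <- generate_grasp_scenario(grasp_scenario("cylinder", 100,
                                                  noise_sd = 0, seed = 1))
  plateau50 <- tr50$data[, 5000]
  plateau100 <- tr100$data[, 5000]
  expect_true(all(plateau50 > plateau100))
  # plateau constant after onset in the noise-free active mode
  expect_lt(max(abs(tr50$data[, 3000] - tr50$data[, 9000])), 1e-9)
  # deterministic from the seed
  tr50b <- generate_grasp_scenario(grasp_scenario("cylinder", 50,
                                                  noise_sd = 0, seed = 1))
  expect_identical(tr50$data, tr50b$data)
  sA <- generate_grasp_scenario(grasp_scenario("sphere", 70, seed = 9))
  sB <- generate_grasp_scenario(grasp_scenario("sphere", 70, seed = 9))
  sC <- generate_grasp_scenario(grasp_scenario("sphere", 70, seed = 10))
  expect_identical(sA$data, sB$data)
  expect_false(identical(sA$data, sC$data))
})

test_that("spheres decay along both axes, cylinders across one", {
  cyl <- generate_grasp_scenario(grasp_scenario("cylinder", 70, noise_sd = 0,
                                                seed = 1))
  sph <- generate_grasp_scenario(grasp_scenario("sphere", 70, noise_sd = 0,
                                                seed = 1))
  cm <- matrix(cyl$data[, 5000], 6, 6, byrow = TRUE)  # rows x cols
  sm <- matrix(sph$data[, 5000], 6, 6, byrow = TRUE)
  # cylinder: constant along its axis (rows), decaying across columns
  expect_lt(max(abs(cm[1, ] - cm[6, ])), 1e-9)
  expect_gt(cm[1, 3], cm[1, 1])
  # sphere: decays along both axes
  expect_gt(sm[3, 3], sm[1, 3])
  expect_gt(sm[3, 3], sm[3, 1])
})

test_that("reactive scenarios add an impact transient and dropout", {
  act <- generate_grasp_scenario(grasp_scenario("sphere", 70, noise_sd = 0,
                                                seed = 1))
  rea <- generate_grasp_scenario(grasp_scenario("sphere", 70,
                                                mode = "reactive",
                                                noise_sd = 0, seed = 1))
  expect_identical(act$data[, 1:4000], rea$data[, 1:4000])
  post <- 5001:6000  # 500-600 ms
  expect_gt(max(rea$data[15, post]), 2 * max(act$data[15, post]))
  expect_equal(rea$events$impact, 500)
  expect_error(grasp_scenario(mode = "reactive", impact_time_ms = 1500,
                              duration_ms = 1000), "before the end")
})

test_that("winning cuneate rate decreases with diameter", {
  rates <- vapply(c(50, 75, 100), function(d) {
    sc <- grasp_scenario("cylinder", d, noise_sd = 0, seed = 1)
    simulate_touch(sc)$cuneate_rate
  }, numeric(1))
  expect_true(all(diff(rates) < 0))
})

test_that("synergy EMG round-trips through the extraction pipeline", {
  act <- grasp_activation_profile(duration_s = 3, fs = 1000)
  emg <- generate_synergy_emg(act, noise_fraction = 0.1, seed = 4)
  expect_equal(dim(emg$signal), c(3L, 3000L))
  expect_identical(emg$labels, c("FDP", "FDS", "FPL"))
  env <- emg_envelope(emg)
  f <- nmf(env, k = 1, seed = 4, restarts = 5)
  expect_gt(vaf(env, f$W, f$H), 0.9)
  # zero activation leaves only the noise floor
  quiet <- generate_synergy_emg(rep(0, 2000), noise_fraction = 0.1, seed = 4)
  expect_lt(max(abs(quiet$signal)), 0.25 * max(abs(emg$signal)))
  # seeded determinism
  e2 <- generate_synergy_emg(act, noise_fraction = 0.1, seed = 4)
  expect_identical(emg$signal, e2$signal)
})
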