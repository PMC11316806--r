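# Cuneate layer: PSP kernel shape, convolution, recruitment arithmetic,
# mapping, signed integration and winner-take-all.

test_that("psp_kernel has the double-exponential shape", {
  k <- psp_kernel(tau_fast = 4, tau_slow = 12.5, dt = 0.1)
  expect_equal(k$values[1], 0)
  expect_true(all(k$values >= 0))
  expect_equal(max(k$values), 1)
  # single interior maximum at the closed-form peak time
  peak_idx <- which.max(k$values)
  expect_gt(peak_idx, 1)
  expect_lt(peak_idx, length(k$values))
  expect_lt(abs(k$times[peak_idx] - psp_peak_time(k)), k$dt)
  expect_true(all(diff(k$values[1:peak_idx]) > 0))
  expect_true(all(diff(k$values[peak_idx:length(k$values)]) < 0))
  expect_lt(k$values[length(k$values)], 0.01)
  expect_error(psp_kernel(tau_fast = 12.5, tau_slow = 4), "smaller")
  expect_error(psp_kernel(horizon = 20), "5 \\* tau_slow")
})

test_that("convolution equals shift-and-add superposition", {
  k <- psp_kernel(dt = 0.1)
  dur <- 500
  empty <- spike_train(numeric(0), dur)
  expect_equal(convolve_spike_train(empty, k), numeric(5000))
  one <- spike_train(120, dur)
  expect_equal(convolve_spike_train(one, k),
               oracle_convolve(120, k$values, 0.1, 5000), tolerance = 1e-9)
  two <- spike_train(c(120, 128.5), dur)
  expect_equal(convolve_spike_train(two, k),
               oracle_convolve(c(120, 128.5), k$values, 0.1, 5000),
               tolerance = 1e-9)
})

test_that("convolution is linear over merged spike trains", {
  k <- psp_kernel(dt = 0.1)
  set.seed(11)
  t1 <- random_train(12, 900); t2 <- random_train(9, 900)
  merged <- sort(c(t1, t2))
  a <- convolve_spike_train(spike_train(t1, 1000), k)
  b <- convolve_spike_train(spike_train(t2, 1000), k)
  m <- convolve_spike_train(spike_train(merged, 1000), k)
  expect_equal(m, a + b, tolerance = 1e-9)
})

test_that("recruited_count applies the ceiling convention", {
  expect_identical(recruited_count(100, 1700, 300), 567L)
  expect_identical(recruited_count(0), 0L)
  expect_identical(recruited_count(300, 1700, 300), 1700L)
  expect_identical(recruited_count(36), 204L)
  expect_error(recruited_count(10, 1700, 0), "> 0")
})

test_that("build_mapping respects the convergence cap and is seeded", {
  m <- build_mapping(36, seed = 5)
  expect_equal(m$n_cuneate, 204L)
  expect_true(all(vapply(m$adjacency, length, integer(1)) == 36L))
  m2 <- build_mapping(36, seed = 5)
  expect_identical(m$adjacency, m2$adjacency)
  m3 <- build_mapping(36, convergence = 10, seed = 9)
  lens <- vapply(m3$adjacency, function(a) length(unique(a)), integer(1))
  expect_true(all(lens == 10L))
  expect_true(all(unlist(m3$adjacency) %in% 1:36))
  m4 <- build_mapping(36, convergence = 10, seed = 10)
  expect_false(identical(m3$adjacency, m4$adjacency))
})

test_that("integrate_psp sums signed weighted inputs", {
  psp <- matrix(runif(36 * 100), nrow = 36)
  map <- build_mapping(36, seed = 1)
  tot <- integrate_psp(psp, map)
  expect_equal(dim(tot), c(204L, 100L))
  # all-excitatory full connectivity: every cuneate sees the plain sum
  expect_equal(tot[1, ], colSums(psp))
  expect_equal(tot[204, ], colSums(psp))
  # single afferent, unit weight: identity
  map1 <- build_mapping(1, divergence = 1, convergence = 1, seed = 1)
  expect_equal(integrate_psp(psp[1, , drop = FALSE], map1)[1, ], psp[1, ])
  # an inhibitory edge of weight -1 cancels a duplicated excitatory afferent
  map_i <- build_mapping(2, divergence = 1, convergence = 2, seed = 1)
  map_i$weights[[1]] <- c(1, -1)
  dup <- rbind(psp[1, ], psp[1, ])
  expect_equal(integrate_psp(dup, map_i)[1, ], rep(0, 100))
})

test_that("winner_take_all maximises the integrated PSP with index ties low", {
  expect_equal(winner_take_all(matrix(1:10, nrow = 1))$winner, 1L)
  two <- rbind(c(1, 2, 3), c(1, 2, 3))
  expect_equal(winner_take_all(two)$winner, 1L)
  set.seed(21)
  series <- matrix(runif(50 * 200), nrow = 50)
  w <- winner_take_all(series, dt = 0.1)
  oracle <- which.max(apply(series, 1, function(y) pracma::trapz(0.1 * (0:199), y)))
  expect_equal(w$winner, oracle)
  expect_equal(w$series, series[oracle, ])
  # permutation equivariance
  perm <- sample(50)
  w2 <- winner_take_all(series[perm, ], dt = 0.1)
  expect_equal(perm[w2$winner], w$winner)
})

test_that("simulate_cuneate delegates to the Izhikevich stage", {
  expect_identical(simulate_cuneate(rep(0, 5000))$times, numeric(0))
  # default parameters equal the SAI-optimised set
  p <- izh_params_sai("cuneate")
  expect_equal(p[c("a", "b", "c", "d", "K")],
               izh_params_sai()[c("a", "b", "c", "d", "K")])
  psp <- rep(30, 10000)
  counts <- vapply(c(0.005, 0.01, 0.02, 0.04), function(g) {
    length(simulate_cuneate(psp, gain = g)$times)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_gt(counts[4], counts[1])
})

test_that("cuneate maps serialize losslessly", {
  m <- build_mapping(12, convergence = 5, inhibitory_fraction = 0.2, seed = 3)
  path <- tempfile(fileext = ".json")
  write_cuneate_map(m, path)
  m2 <- read_cuneate_map(path)
  expect_identical(m$adjacency, m2$adjacency)
  expect_equal(m$weights, m2$weights)
  expect_equal(m$n_cuneate, m2$n_cuneate)
})
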