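# Signal-detection-theory discrimination: d-prime, hit rates, and the
# noise/signal bookkeeping of the touch protocol.

test_that("dprime follows the rms-of-sds definition", {
  x <- c(1, 2, 3, 4)
  expect_equal(dprime(x, x), 0)
  set.seed(41)
  s <- rnorm(2000, 1, 1); n <- rnorm(2000, 0, 1)
  expect_lt(abs(dprime(s, n) - 1), 0.1)
  s2 <- c(3, 4, 5); n2 <- c(0, 1, 2)
  # hand formula: means 3 apart, sds 1 and 1 -> exactly 3
  expect_equal(dprime(s2, n2), 3)
  s3 <- c(0, 2, 4) + 2  # mean 4, sd 2
  n3 <- c(0, 1, 2)      # mean 1, sd 1
  expect_equal(dprime(s3, n3), 3 / sqrt((4 + 1) / 2))
  expect_error(dprime(c(1, 1), c(1, 1)), "zero pooled sd")
  expect_error(dprime(1, c(1, 2)), "at least 2")
})

test_that("hit_rate_from_dprime is the unbiased percent correct", {
  expect_equal(hit_rate_from_dprime(0), 0.5)
  expect_equal(hit_rate_from_dprime(1), pnorm(0.5))
  expect_gt(hit_rate_from_dprime(10), 0.999)
  d <- seq(-2, 4, 0.5)
  expect_true(all(diff(hit_rate_from_dprime(d)) > 0))
})

test_that("swapping signal and noise negates d-prime and reflects the hit rate", {
  set.seed(42)
  s <- rnorm(50, 2); n <- rnorm(50, 0)
  expect_equal(dprime(s, n), -dprime(n, s))
  expect_equal(hit_rate_from_dprime(dprime(s, n)) - 0.5,
               0.5 - hit_rate_from_dprime(dprime(n, s)))
})

test_that("vp_noise_signal_sets produces the protocol's distance counts", {
  set.seed(43)
  mk <- function(n) lapply(seq_len(n), function(i)
    spike_train(random_train(8), 1000))
  trains <- list("100" = mk(10), "50" = mk(10), "70" = mk(10))
  sets <- vp_noise_signal_sets(trains, "100", q = 0.05)
  expect_length(sets$noise, choose(10, 2))   # 45 baseline pairs
  expect_length(sets$signal[["50"]], 10)     # indexed pairing
  expect_length(sets$signal[["70"]], 10)
  cross <- vp_noise_signal_sets(trains, "100", q = 0.05, pairing = "cross")
  expect_length(cross$signal[["50"]], 100)
  # all-identical trains: distances all zero, d-prime degenerates
  same <- lapply(1:10, function(i) spike_train(c(100, 300), 1000))
  degen <- vp_noise_signal_sets(list("100" = same, "50" = same), "100")
  expect_true(all(degen$noise == 0) && all(degen$signal[["50"]] == 0))
  expect_error(dprime(degen$signal[["50"]], degen$noise), "zero pooled sd")
})

test_that("diameter-independent responses give chance-level hit rates", {
  # same response law for every diameter, independent draws per touch
  src <- function(shape, diameter_mm, touch) {
    set.seed(diameter_mm * 1000 + touch * 7 + 5000)
    spike_train(random_train(20 + sample(-3:3, 1)), 1000)
  }
  proto <- discrimination_protocol(shapes = "cylinder",
                                   diameters_mm = c(50, 70, 100),
                                   touches_per_object = 10, seed = 1)
  res <- run_discrimination_protocol(proto, src)
  expect_true(all(abs(res$d_prime) < 1.5))
  expect_true(all(abs(res$hit_rate - 0.5) < 0.35))
  expect_lt(abs(mean(res$hit_rate) - 0.5), 0.2)
})

test_that("curvature-scaled responses give monotone hit rates and full bookkeeping", {
  src <- function(shape, diameter_mm, touch) {
    seed <- diameter_mm * 37 + touch + ifelse(shape == "sphere", 10000, 0)
    set.seed(seed)
    n <- rpois(1, 40 - 0.25 * diameter_mm)
    spike_train(random_train(n), 1000)
  }
  proto <- discrimination_protocol(diameters_mm = c(50, 60, 70, 80, 90, 100),
                                   touches_per_object = 10, seed = 2)
  res <- run_discrimination_protocol(proto, src)
  expect_equal(nrow(res), 2 * 5 * 2)  # 2 shapes x 5 targets x 2 features
  vp_rows <- res[res$feature == "vp", ]
  expect_equal(sum(vp_rows$n_signal), 100)               # across both shapes
  expect_equal(sum(vp_rows$n_signal[vp_rows$shape == "cylinder"]), 50)
  for (sh in c("cylinder", "sphere")) {
    hr <- res$hit_rate[res$shape == sh & res$feature == "rate"]
    expect_gt(hr[1], hr[5])  # 50 mm discriminated best
    expect_lt(cor(seq_along(hr), hr, method = "spearman"), 0)
  }
  # reproducible from the protocol alone
  res2 <- run_discrimination_protocol(proto, src)
  expect_equal(res, res2, ignore_attr = TRUE)
})

test_that("protocol validation catches inconsistent definitions", {
  expect_error(discrimination_protocol(diameters_mm = c(50, 60),
                                       baseline_diameter_mm = 100),
               "baseline")
  expect_error(discrimination_protocol(touches_per_object = 1), "at least 2")
})
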