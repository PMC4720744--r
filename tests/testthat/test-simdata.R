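test_that("simulation spec validates its parameters", {
  expect_error(simulation_spec(phi = 1), class = "scedab_invalid-spec")
  expect_error(simulation_spec(phi = -1.2), class = "scedab_invalid-spec")
  expect_error(simulation_spec(noise_sd = -1), class = "scedab_invalid-spec")
  expect_error(simulation_spec(n_pre = 0), class = "scedab_invalid-spec")
  expect_error(simulation_spec(level = Inf), class = "scedab_invalid-spec")
})

test_that("the deterministic part follows the AB decomposition", {
  s <- simulate_ab(simulation_spec(n_pre = 3, n_post = 3, level = 0, trend = 2,
                                   level_change = 4, slope_change = -2,
                                   noise_sd = 0))
  expect_equal(s$score, c(0, 2, 4, 10, 10, 10))

  const <- simulate_ab(simulation_spec(n_pre = 4, n_post = 4, level = 7,
                                       noise_sd = 0))
  expect_equal(const$score, rep(7, 8))
})

test_that("identical specs and seeds give bit-identical series", {
  spec <- simulation_spec(n_pre = 6, n_post = 9, level = 50, trend = -1,
                          level_change = -5, phi = 0.4, noise_sd = 2, seed = 99)
  expect_identical(simulate_ab(spec)$score, simulate_ab(spec)$score)
  spec2 <- simulation_spec(n_pre = 6, n_post = 9, level = 50, trend = -1,
                           level_change = -5, phi = 0.4, noise_sd = 2, seed = 100)
  expect_false(identical(simulate_ab(spec)$score, simulate_ab(spec2)$score))
})

test_that("AR(1) noise shows the configured lag-1 autocorrelation", {
  s <- simulate_ab(simulation_spec(n_pre = 2500, n_post = 2500, phi = 0.9,
                                   noise_sd = 1, seed = 5))
  rho <- stats::acf(s$score, lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(abs(rho - 0.9), 0.03)

  iid <- simulate_ab(simulation_spec(n_pre = 2500, n_post = 2500, phi = 0,
                                     noise_sd = 1, seed = 6))
  expect_lt(abs(stats::acf(iid$score, lag.max = 1, plot = FALSE)$acf[2]), 0.05)
})

test_that("slc recovers every generating triple on a grid when noiseless", {
  grid <- expand.grid(b = c(-3, -0.5, 0, 1, 2.5),
                      sc = c(-2, -1, 0, 0.5, 3),
                      lc = c(-15, -2, 0, 4, 10))
  for (i in seq_len(nrow(grid))) {
    s <- simulate_ab(simulation_spec(n_pre = 5, n_post = 10, level = 60,
                                     trend = grid$b[i],
                                     level_change = grid$lc[i],
                                     slope_change = grid$sc[i], noise_sd = 0))
    r <- slc(s)
    expect_equal(r$baseline_trend, grid$b[i])
    expect_equal(r$slope_change, grid$sc[i])
    expect_equal(r$level_change, grid$lc[i])
  }
})

test_that("null calibration of NAP converges to the 50% chance level", {
  cal <- null_nap_calibration(n_pre = 5, n_post = 10, reps = 2000, seed = 8)
  expect_lt(abs(cal$mean_nap - 0.5), 3 * cal$se)
  expect_true(cal$se_defined)

  one <- null_nap_calibration(reps = 1, seed = 9)
  expect_false(one$se_defined)
  expect_true(is.na(one$se))
})

test_that("stochastic dominance drives mean NAP to 1", {
  set.seed(10)
  vals <- replicate(200, {
    pre <- rnorm(5, mean = 0)
    post <- rnorm(10, mean = -10)  # shifted 10 sd down, aim = decrease
    nap(two_phase_series(pre, post, aim = "decrease"))$nap
  })
  expect_gt(mean(vals), 0.999)
})

test_that("sd band calibration approaches normal-theory exceedance with long baselines", {
  cal <- sd_band_null_calibration(n_pre = 500, n_post = 10, reps = 400, seed = 12)
  expect_lt(cal$outside_fraction, 0.05)
  # and with a typically short baseline the estimated band is too narrow
  short <- sd_band_null_calibration(n_pre = 5, n_post = 10, reps = 400, seed = 12)
  expect_gt(short$outside_fraction, 0.05)
})
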