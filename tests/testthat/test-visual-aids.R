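test_that("range lines report per-phase extrema and overlap", {
  r <- range_lines(two_phase_series(c(1, 3), c(4, 6)))
  expect_equal(r$minimum, c(1, 4))
  expect_equal(r$maximum, c(3, 6))
  expect_false(r$ranges_overlap[1])

  expect_true(range_lines(two_phase_series(c(1, 5), c(4, 6)))$ranges_overlap[1])
  single <- range_lines(two_phase_series(2, 9))
  expect_equal(single$minimum, single$maximum)
})

test_that("sd band is built from the baseline and counts strict exceedances", {
  b <- sd_band(two_phase_series(c(1, 2, 3), c(5, 3)))
  expect_equal(b$center, 2)
  expect_equal(b$sd, 1)
  expect_equal(c(b$lower, b$upper), c(0, 4))
  expect_equal(b$outside_post, 1L)
  expect_equal(b$outside_fraction, 0.5)
  expect_equal(b$direction, "above")

  degenerate <- sd_band(two_phase_series(c(4, 4, 4), 4))
  expect_equal(degenerate$lower, degenerate$upper)
  expect_equal(degenerate$outside_fraction, 0)  # point exactly on the band is inside

  expect_error(sd_band(two_phase_series(1, c(2, 3))),
               class = "scedab_baseline-too-short")

  med <- sd_band(two_phase_series(c(1, 2, 9), c(5, 3)), center = "median")
  expect_equal(med$center, 2)
})

test_that("sd band limits are symmetric and shift with the data", {
  set.seed(31)
  for (i in 1:20) {
    s <- random_series()
    b <- sd_band(s)
    expect_equal(b$upper - b$center, b$center - b$lower)
    c_shift <- runif(1, -10, 10)
    b2 <- sd_band(two_phase_series(pre_scores(s) + c_shift,
                                   post_scores(s) + c_shift))
    expect_equal(b2$center, b$center + c_shift)
    expect_equal(b2$lower, b$lower + c_shift)
    expect_equal(b2$upper, b$upper + c_shift)
    expect_equal(b2$outside_post, b$outside_post)
  }
})

test_that("ols trend matches the closed-form simple regression", {
  f <- ols_trend(c(1, 3, 5))
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, -1)
  expect_equal(ols_trend(rep(4, 5))$slope, 0)
  two <- ols_trend(c(2, 7), offset = 3)
  expect_equal(predict(two, c(4, 5)), c(2, 7))  # exact interpolation
  expect_error(ols_trend(3), class = "scedab_phase-too-short")

  set.seed(37)
  for (i in 1:50) {
    y <- rnorm(sample(2:12, 1))
    t <- seq_along(y)
    f <- ols_trend(y)
    # independent closed form: slope = cov/var, intercept = ybar - slope tbar
    slope <- sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
    expect_equal(f$slope, slope)
    expect_equal(f$intercept, mean(y) - slope * mean(t))
  }
})

test_that("split-middle passes through the half-phase median points", {
  even <- split_middle(c(1, 2, 3, 4))
  expect_equal(even$slope, 1)
  expect_equal(even$intercept, 0)

  odd <- split_middle(c(2, 4, 6, 8, 10))  # middle point in both halves
  expect_equal(odd$slope, 2)
  expect_equal(odd$intercept, 0)

  flat <- split_middle(rep(5, 4))
  expect_equal(flat$slope, 0)
  expect_equal(predict(flat, 10), 5)

  dropped <- split_middle(c(2, 4, 6, 8, 10), middle = "drop")
  expect_equal(dropped$slope, 2)  # halves {1,2},{4,5}: (1.5,3),(4.5,9)
  expect_error(split_middle(7), class = "scedab_phase-too-short")
})

test_that("split-middle recovers any exact line for odd and even lengths", {
  set.seed(41)
  for (n in 2:11) {
    slope <- runif(1, -5, 5)
    intercept <- runif(1, -10, 10)
    offset <- sample(0:5, 1)
    y <- intercept + slope * (offset + seq_len(n))
    for (mid in c("both", "drop")) {
      f <- split_middle(y, offset = offset, middle = mid)
      expect_equal(f$slope, slope)
      expect_equal(f$intercept, intercept)
    }
  }
})

test_that("stability envelope projects the baseline trend with 25%-of-median limits", {
  e <- stability_envelope(two_phase_series(c(1, 2, 3, 4), c(5.5, 7),
                                           aim = "increase"))
  expect_equal(e$half_width, 0.625)
  expect_equal(e$trend$slope, 1)
  expect_equal(e$baseline_within_fraction, 1)
  expect_equal(e$post_within_fraction, 0.5)  # t=5 holds 5.5, t=6 excludes 7
  expect_false(e$stable)
  expect_equal(e$direction, "above")

  on_line <- stability_envelope(linear_series(4, 4, 1.5, 2))
  expect_equal(on_line$baseline_within_fraction, 1)
  expect_equal(on_line$post_within_fraction, 1)
  expect_true(on_line$stable)
})

test_that("enlarging the envelope fraction never shrinks containment", {
  set.seed(43)
  for (i in 1:20) {
    s <- two_phase_series(runif(sample(4:10, 1), 1, 10),
                          runif(sample(4:10, 1), 1, 10))
    fr <- sort(runif(2, 0.05, 1))
    e1 <- stability_envelope(s, fraction = fr[1])
    e2 <- stability_envelope(s, fraction = fr[2])
    expect_gte(e2$baseline_within_fraction, e1$baseline_within_fraction)
    expect_gte(e2$post_within_fraction, e1$post_within_fraction)
  }
})

test_that("immediacy contrasts the windows around the phase boundary", {
  i <- immediacy(two_phase_series(c(10, 10, 10, 8, 8), c(4, 4, 4, 4),
                                  aim = "decrease"))
  expect_equal(i$change, 4 - 26 / 3)
  expect_equal(i$label, "improvement")

  flat <- immediacy(two_phase_series(rep(5, 4), rep(5, 4)))
  expect_equal(flat$change, 0)
  expect_equal(flat$label, "no change")

  one <- immediacy(two_phase_series(3, c(9, 1)), window = 1)
  expect_equal(one$change, 6)
  expect_equal(one$label, "deterioration")

  expect_error(immediacy(two_phase_series(c(1, 2), c(1, 2, 3)), window = 3),
               class = "scedab_window-too-large")
})
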