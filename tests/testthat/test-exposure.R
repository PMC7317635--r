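test_that("step and MET-minute unit conversions are exact", {
  expect_equal(round(steps_to_met_minutes(1404, 34.5)), 285)
  expect_equal(steps_to_met_minutes(0, 34.5), 0)
  expect_equal(steps_to_met_minutes(34.5, 34.5), 7)
  expect_error(steps_to_met_minutes(100, 0), "positive")
  expect_error(steps_to_met_minutes(-1), "non-negative")

  expect_equal(round(met_minutes_to_activity_hours(285, 3.0), 1), 1.6)
  expect_equal(round(met_minutes_to_activity_hours(285, 4.5), 1), 1.1)
  expect_equal(met_minutes_to_activity_hours(0, 3.0), 0)
  expect_error(met_minutes_to_activity_hours(285, 0), "positive")
})

test_that("exposure distributions validate their invariants", {
  expect_error(exposure_distribution(rep(0.2, 8)), "sum to 1")
  expect_error(exposure_distribution(c(-0.1, 1.1, rep(0, 6))), "non-negative")
  d <- exposure_distribution(c(1, rep(0, 7)))
  expect_equal(sum(d$proportion), 1)
  expect_equal(mean_exposure(d), 0)
})

test_that("shift_distribution reallocates mass as specified", {
  d <- exposure_distribution(rep(1 / 8, 8))
  expect_identical(shift_distribution(d, 300, 0), d)
  expect_identical(shift_distribution(d, 0, 0.5), d)

  # big enough delta pushes everything into the absorbing top bin
  all_top <- shift_distribution(d, 1e6, 1)
  expect_equal(all_top$proportion, c(rep(0, 7), 1))

  # two-bin toy: (0.6 @ 0, 0.4 @ 600), delta 600, fraction 0.5 -> (0.3, 0.7)
  bins <- data.frame(lower = c(0, 600), upper = c(600, Inf),
                     midpoint = c(0, 600))
  toy <- exposure_distribution(c(0.6, 0.4), bins)
  shifted <- shift_distribution(toy, 600, 0.5)
  expect_equal(shifted$proportion, c(0.3, 0.7))

  expect_error(shift_distribution(d, -1, 0.5), "non-negative")
  expect_error(shift_distribution(d, 10, 1.5), "0, 1")
})

test_that("shift_distribution conserves mass and is monotone in delta", {
  set.seed(42)
  for (rep in 1:25) {
    d <- random_exposure()
    frac <- runif(1)
    deltas <- sort(runif(3, 0, 5000))
    means <- vapply(deltas, function(dl) {
      s <- shift_distribution(d, dl, frac)
      expect_equal(sum(s$proportion), 1, tolerance = 1e-12)
      mean_exposure(s)
    }, numeric(1))
    expect_true(all(diff(means) >= -1e-12))
    expect_true(all(means >= mean_exposure(d) - 1e-12))
  }
})

test_that("compute_pif matches its closed forms and the null cases", {
  bins <- data.frame(lower = c(0, 600), upper = c(600, Inf),
                     midpoint = c(0, 600))
  bau <- exposure_distribution(c(0.5, 0.5), bins)
  cf <- exposure_distribution(c(0, 1), bins)
  rr_half <- relative_risk_function("d", slope = log(2) / 600, floor = 0.5)
  # RR = (1, 0.5): PIF = (0.75 - 0.5) / 0.75 = 1/3
  expect_equal(compute_pif(bau, cf, rr_half), 1 / 3, tolerance = 1e-15)
  expect_equal(compute_pif(bau, bau, rr_half), 0)
  rr_null <- relative_risk_function("d", slope = 0)
  expect_equal(compute_pif(bau, cf, rr_null), 0)
  wrong_bins <- exposure_distribution(c(0.5, 0.5),
    data.frame(lower = c(0, 300), upper = c(300, Inf), midpoint = c(0, 300)))
  expect_error(compute_pif(bau, wrong_bins, rr_half), "bin structure")
})

test_that("compute_pif agrees with the brute-force expected-risk oracle", {
  set.seed(7)
  for (rep in 1:50) {
    bau <- random_exposure()
    cf <- random_exposure()
    rr <- relative_risk_function("d", slope = runif(1, 0, 2e-3),
                                 floor = runif(1, 0.3, 0.9))
    expect_equal(compute_pif(bau, cf, rr),
                 pif_oracle(bau$proportion, cf$proportion,
                            rr_evaluate(rr, bau$midpoint)),
                 tolerance = 1e-12)
  }
})

test_that("relative-risk functions are anchored, monotone and floored", {
  rr <- relative_risk_function("chd", slope = log(2) / 600)
  e <- seq(0, 6000, by = 50)
  v <- rr_evaluate(rr, e)
  expect_equal(v[1], 1)
  expect_true(all(diff(v) <= 0))
  expect_true(all(v >= 0.5))
  expect_error(relative_risk_function("x", slope = -1), "non-negative")
})

test_that("lagged PIFs average the window with zero-padding", {
  lag05 <- lag_window(0, 5)
  # constant series: mean of a constant is the constant
  expect_equal(lag_pif_series(rep(0.2, 50), lag05, 10:20), rep(0.2, 11))
  # one-year pulse p at year 0 queried at year 2: p / 6
  pulse <- c(0.3, rep(0, 49))
  expect_equal(lag_pif_series(pulse, lag05, 2), 0.3 / 6)
  # cancer window (10, 30) sees nothing of a year-0 pulse at year 5
  expect_equal(lag_pif_series(pulse, lag_window(10, 30), 5), 0)
  expect_error(lag_pif_series(pulse, lag05, -1), "non-negative")
  expect_error(lag_window(5, 5), "min_years < max_years")
})

test_that("the engine's lag filter matches lag_pif_series exactly", {
  set.seed(11)
  for (lag in list(lag_window(0, 5), lag_window(10, 30))) {
    annual <- matrix(runif(3 * 60, 0, 0.5), 3, 60)
    eff <- pamslt:::.lag_pif_matrix(annual, lag)
    for (row in 1:3)
      expect_equal(eff[row, ], lag_pif_series(annual[row, ], lag, 0:59),
                   tolerance = 1e-14)
  }
})
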