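test_that("the kobs trend separates the two release mechanisms", {
  # DNA-dependent release: significant positive slope
  wt_ser <- simulate_preset("WT", "dissociation", seed = 21,
                            n_points = 100)
  tr <- kobs_trend_test(wt_ser)
  expect_true(tr$significant)
  expect_gt(tr$slope, 0)

  # competitor-independent release: flat
  mut_ser <- simulate_preset("W589A", "dissociation", seed = 22,
                             n_points = 100,
                             competitor_molar = c(400, 900, 1900, 4000))
  tr2 <- kobs_trend_test(mut_ser)
  expect_false(tr2$significant)

  # identical kobs: slope exactly zero
  tr3 <- kobs_trend_test(data.frame(conc = c(1, 2, 3, 4),
                                    kobs = rep(2, 4)))
  expect_equal(tr3$slope, 0)
  expect_false(tr3$significant)

  expect_error(kobs_trend_test(data.frame(conc = 1:3, kobs = 1:3)),
               "at least 4")
})

test_that("the runs test is calibrated on independent noise", {
  set.seed(42)
  p <- replicate(400, runs_test(rnorm(200))$p_value)
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.10)
  # one-signed residuals are maximally non-random
  expect_equal(runs_test(rep(1, 50))$p_value, 0)
})

test_that("residual diagnostics expose a wrong mechanism", {
  ser <- simulate_preset("WT", "dissociation", seed = 23, n_points = 100)
  wrong <- global_fit(ser, "simple_competition",
                      fixed = c(k1 = 3.1), n_starts = 2, seed = 23)
  right <- global_fit(ser, "ternary", fixed = c(k1 = 3.1, k_m1 = 0.5),
                      n_starts = 3, seed = 23)
  rep_wrong <- residual_skew_report(wrong)
  rep_right <- residual_skew_report(right)
  expect_gt(mean(rep_wrong$structured), 0.5)
  expect_lt(mean(rep_right$structured), 0.5)
})

test_that("scheme comparison prefers the generating mechanism", {
  ser <- simulate_preset("WT", "dissociation", seed = 24, n_points = 100)
  cmp <- compare_schemes(ser, fixed = c(k1 = 3.1, k_m1 = 0.5),
                         seed = 24, n_starts = 3)
  expect_equal(cmp$preferred, "ternary")
  expect_gt(cmp$delta_aic, 10)
  expect_equal(cmp$table$scheme[1], "ternary")  # ranked by AIC

  mut <- simulate_preset("dWGR", "dissociation", seed = 25,
                         n_points = 100)
  cmp2 <- compare_schemes(mut, fixed = c(k1 = 2.4, k_m1 = 0.5),
                          seed = 25, n_starts = 3)
  expect_equal(cmp2$preferred, "simple_competition")
})

test_that("a single-concentration design is flagged as uninformative", {
  one <- simulate_preset("WT", "dissociation", seed = 26, n_points = 80,
                         competitor_molar = 1000)
  cmp <- compare_schemes(one, fixed = c(k1 = 3.1, k_m1 = 0.5), seed = 26,
                         n_starts = 2)
  expect_true(any(grepl("cannot separate", cmp$verdict)))
})
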