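test_that("single-exponential fitting recovers exact inputs", {
  t <- exp(seq(log(0.001), log(0.2), length.out = 120))
  y <- 0.1 + 0.15 * exp(-50 * t)
  f <- fit_single_exponential(t, y)
  expect_true(f$converged)
  expect_equal(f$kobs, 50, tolerance = 1e-4)
  expect_equal(f$amplitude, 0.15, tolerance = 1e-4)
  expect_equal(f$offset, 0.1, tolerance = 1e-4)

  # flat noisy trace: reported as non-converged with kobs 0, not an error
  set.seed(1)
  flat <- fit_single_exponential(t, rnorm(120, 0.25, 0.004))
  expect_false(flat$converged)
  expect_equal(flat$kobs, 0)
  expect_match(flat$diagnostic, "amplitude|constant")

  expect_error(fit_single_exponential(t[1:5], y[1:5]), "at least 10")
})

test_that("observed association rates reproduce k1*P + k_m1", {
  # pseudo-first-order conditions: protein at >= 20x over the probe
  ser <- generate_association_series(
    rate_params(k1 = 3.1, k_m1 = 5), c(60, 106, 188, 250),
    Dstar_total = 1.5,
    instrument = fast_inst(0.025, n_points = 150, noise_sd = 0))
  ef <- series_exp_fits(ser)
  for (i in seq_len(nrow(ef))) {
    expected <- 3.1 * ef$conc[i] + 5
    expect_lt(abs(ef$kobs[i] - expected) / expected, 0.02)
  }
  # and the replot slope estimates the association rate constant
  rp <- replot_kobs(ef)
  expect_lt(abs(rp$slope - 3.1) / 3.1, 0.03)

  # perfectly collinear input
  rp2 <- replot_kobs(c(1, 2, 3, 4), c(10, 20, 30, 40))
  expect_equal(rp2$r_squared, 1)
  expect_error(replot_kobs(c(1, 2), c(1, 2)), "at least 3")
})

test_that("high-competitor exchange decays as a clean single exponential", {
  ser <- noiseless_dissoc(n_points = 150, concs = c(2000, 4000))
  f <- fit_single_exponential(ser$traces[[2]])
  expect_true(f$converged)
  expect_lt(f$rmse, 0.01 * abs(f$amplitude))
})

test_that("global fits on noiseless data are exact self-recoveries", {
  wt <- wt_params()
  truth <- unlist(wt)

  ser <- noiseless_dissoc(n_points = 60)
  fit <- global_fit(ser, "ternary", fixed = c(k1 = wt$k1, k_m1 = wt$k_m1),
                    n_starts = 4, seed = 2)
  expect_true(fit$converged)
  got <- unlist(fit$params)[c("k2", "k_m2", "k3", "k_m3")]
  expect_equal(unname(got), unname(truth[c("k2", "k_m2", "k3", "k_m3")]),
               tolerance = 1e-4)

  sa <- noiseless_assoc(n_points = 60)
  fa <- global_fit(sa, "association", n_starts = 4, seed = 2)
  expect_equal(unname(unlist(fa$params)[c("k1", "k_m1")]), c(3.1, 5),
               tolerance = 1e-4)

  # the reported optimum is the best entry of the multistart log
  expect_true(all(fit$chi2 <= fit$multistart_log$chi2 + 1e-12))
  expect_equal(fit$n_free, 4L)
  expect_equal(fit$n_data, sum(lengths(lapply(ser$traces, `[[`,
                                              "values"))))
})

test_that("simple-competition fits recover the release rate", {
  ser <- generate_dissociation_series(
    preset("W589A")$params, c(400, 1300, 4000),
    scheme = "simple_competition",
    instrument = fast_inst(1, n_points = 80, noise_sd = 0))
  fit <- global_fit(ser, "simple_competition", fixed = c(k1 = 4.2),
                    n_starts = 2, seed = 1)
  expect_equal(unlist(fit$params)[["k_m1"]], 20.2, tolerance = 1e-4)
})

test_that("profile bounds behave at their degenerate and trivial limits", {
  # noisy series so the residual-variance scaling is non-degenerate
  ser <- generate_association_series(
    rate_params(k1 = 3.1, k_m1 = 5), c(60, 106, 188, 250),
    instrument = fast_inst(0.025, n_points = 60, seed = 31))
  fit <- global_fit(ser, "association", n_starts = 2, seed = 31)

  # zero threshold returns the point estimate
  p0 <- profile_upper_bound(ser, "association", "k_m1", delta_chi2 = 0,
                            fit = fit, n_starts = 2, seed = 31)
  expect_equal(p0$bound, unlist(fit$params)[["k_m1"]])

  # a constant with no influence on the observable is unbounded
  pk3 <- profile_upper_bound(ser, "association", "k3", fit = fit,
                             n_starts = 2, seed = 31)
  expect_equal(pk3$bound, Inf)
  expect_match(pk3$status, "unbounded")
})

test_that("the residual bootstrap is deterministic and degenerates cleanly", {
  ser <- generate_dissociation_series(
    preset("W589A")$params, c(400, 1300, 4000),
    scheme = "simple_competition",
    instrument = fast_inst(1, n_points = 60, seed = 13))
  fit <- global_fit(ser, "simple_competition", fixed = c(k1 = 4.2),
                    n_starts = 2, seed = 13)
  b1 <- bootstrap_uncertainty(ser, "simple_competition", n_boot = 12,
                              seed = 5, fit = fit, fixed = c(k1 = 4.2))
  b2 <- bootstrap_uncertainty(ser, "simple_competition", n_boot = 12,
                              seed = 5, fit = fit, fixed = c(k1 = 4.2))
  expect_equal(b1, b2)
  expect_lte(b1$lower, b1$estimate)
  expect_gte(b1$upper, b1$estimate)
  # the estimate sits on the generating truth at this noise level
  expect_lt(abs(b1$estimate - 20.2) / 20.2, 0.02)
  expect_error(bootstrap_uncertainty(ser, "simple_competition",
                                     n_boot = 5, fit = fit), "n_boot")

  # noiseless data give essentially zero-width intervals
  ser0 <- generate_dissociation_series(
    preset("W589A")$params, c(400, 1300, 4000),
    scheme = "simple_competition",
    instrument = fast_inst(1, n_points = 60, noise_sd = 0))
  f0 <- global_fit(ser0, "simple_competition", fixed = c(k1 = 4.2),
                   n_starts = 2, seed = 1)
  b0 <- bootstrap_uncertainty(ser0, "simple_competition", n_boot = 10,
                              seed = 1, fit = f0, fixed = c(k1 = 4.2))
  expect_lt(b0$upper - b0$lower, 1e-5 * b0$estimate)
})
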