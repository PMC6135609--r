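test_that("trace generation is deterministic under a fixed seed", {
  a <- simulate_preset("WT", "dissociation", seed = 3, n_points = 40)
  b <- simulate_preset("WT", "dissociation", seed = 3, n_points = 40)
  expect_identical(lapply(a$traces, `[[`, "values"),
                   lapply(b$traces, `[[`, "values"))
  c <- simulate_preset("WT", "dissociation", seed = 4, n_points = 40)
  expect_false(identical(a$traces[[1]]$values, c$traces[[1]]$values))
})

test_that("noise scales as noise_sd over sqrt(shots averaged)", {
  p <- rate_params(k1 = 3.1, k_m1 = 5)
  concs <- seq(60, 250, length.out = 25)
  inst_noisy <- instrument_spec(t_end = 0.025, n_points = 500, seed = 2)
  inst_clean <- instrument_spec(t_end = 0.025, n_points = 500, seed = 2,
                                noise_sd = 0)
  noisy <- generate_association_series(p, concs, instrument = inst_noisy)
  clean <- generate_association_series(p, concs, instrument = inst_clean)
  resid <- unlist(lapply(seq_along(concs), function(i) {
    noisy$traces[[i]]$values - clean$traces[[i]]$values
  }))
  expect_gte(length(resid), 1e4)
  target <- inst_noisy$noise_sd / sqrt(inst_noisy$shots_averaged)
  expect_lt(abs(sd(resid) - target) / target, 0.10)
})

test_that("protein-free traces sit on the free-probe baseline", {
  p <- rate_params(k1 = 3.1, k_m1 = 5)
  ser <- generate_association_series(p, c(0, 83),
                                     instrument = fast_inst(0.025,
                                                            n_points = 400,
                                                            seed = 6))
  base <- ser$traces[[1]]$values
  sem <- sd(base) / sqrt(length(base))
  expect_lt(abs(mean(base) - 0.05), 3 * sem)
})

test_that("no sample ever precedes the mixing dead time", {
  inst <- instrument_spec(t_end = 5, dead_time = 0.002, n_points = 50)
  ser <- generate_dissociation_series(wt_params(), c(500, 2000),
                                      instrument = inst)
  for (tr in ser$traces) expect_gte(min(tr$times), 0.002)
  expect_equal(length(ser$traces[[1]]$times), 50L)
})

test_that("noiseless traces are smooth single-phase curves", {
  ser <- noiseless_assoc()
  f <- fit_single_exponential(ser$traces[[4]])
  expect_lt(f$rmse, 0.01 * abs(f$amplitude))
})

test_that("release requires competitor sites in stoichiometric excess", {
  wt <- wt_params()
  inst <- fast_inst(5, n_points = 120, seed = 8)
  span <- 0.2

  # no competitor: flat high-anisotropy trace (excess protein holds probe)
  ser0 <- generate_dissociation_series(wt, list(competitor_spec(0)),
                                       scheme = "ternary",
                                       instrument = inst)
  f0 <- fit_single_exponential(ser0$traces[[1]])
  expect_false(f0$converged)
  expect_equal(f0$kobs, 0)
  expect_gt(mean(ser0$traces[[1]]$values), 0.2)  # near bound plateau

  # 5 nM oligomer: no observable release; 5 nM x 200 sites: release
  # comparable to 1 uM oligomer
  ser <- generate_dissociation_series(
    wt, list(competitor_spec(5, 1), competitor_spec(1000, 1)),
    scheme = "ternary", instrument = inst)
  ser_pl <- generate_dissociation_series(
    wt, list(competitor_spec(5, 200)), scheme = "ternary",
    instrument = inst)
  f5 <- fit_single_exponential(ser$traces[[1]])
  expect_lt(abs(f5$amplitude), 0.05 * span)
  f_plasmid <- fit_single_exponential(ser_pl$traces[[1]])
  f_oligo <- fit_single_exponential(ser$traces[[2]])
  expect_lt(abs(f_plasmid$kobs - f_oligo$kobs) / f_oligo$kobs, 0.10)
  expect_gt(abs(f_plasmid$amplitude), 0.5 * span)
})

test_that("WGR-deficient release is competitor-independent", {
  ser <- simulate_preset("dWGR", "dissociation", seed = 5, n_points = 120)
  ef <- series_exp_fits(ser)
  expect_true(all(ef$converged))
  expect_lt(max(ef$kobs) / min(ef$kobs), 1.1)   # 0.4-4 uM superimpose
})

test_that("series round-trip through CSV + manifest losslessly", {
  ser <- simulate_preset("WT_plasmid", "dissociation", seed = 7,
                         n_points = 30)
  ser$traces[[1]]$meta$operator <- "rig A"   # unknown metadata survives
  path <- withr::local_tempdir()
  write_series(ser, path)
  back <- read_series(path)
  expect_identical(lapply(ser$traces, `[[`, "times"),
                   lapply(back$traces, `[[`, "times"))
  expect_identical(lapply(ser$traces, `[[`, "values"),
                   lapply(back$traces, `[[`, "values"))
  expect_identical(back$traces[[1]]$meta$operator, "rig A")
  expect_identical(back$traces[[1]]$meta$competitor_sites, 450L)
  expect_equal(back$scheme, "ternary")
  expect_equal(back$instrument$n_points, 30L)

  # manifest naming a missing file is an explicit error
  file.remove(file.path(path, "trace_02.csv"))
  expect_error(read_series(path), "trace_02.csv")
})
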