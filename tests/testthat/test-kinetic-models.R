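test_that("reaction networks match the three mechanisms", {
  rn1 <- reaction_network("association")
  expect_equal(nrow(rn1), 1L)
  expect_true(rn1$reversible)
  expect_setequal(unlist(strsplit(c(rn1$reactants, rn1$products),
                                  " \\+ ")), c("P", "Dstar", "PDstar"))

  rn2 <- reaction_network("simple_competition")
  expect_true(any(!rn2$reversible))            # irreversible competitor trap
  expect_true(all(is.na(rn2$k_reverse[!rn2$reversible])))

  rn3 <- reaction_network("ternary")
  expect_equal(nrow(rn3), 4L)
  expect_true(all(rn3$reversible))
  expect_setequal(unlist(strsplit(c(rn3$reactants, rn3$products),
                                  " \\+ ")),
                  c("P", "Dstar", "D", "PDstar", "PD", "T"))
  # direction convention: k3 releases the labeled DNA from T
  row <- rn3[rn3$reactants == "PD + Dstar", ]
  expect_equal(row$k_forward, "k_m3")
  expect_equal(row$k_reverse, "k3")

  expect_error(reaction_network("banana"), "valid schemes")
})

test_that("mass-action derivatives are correct and conserve mass", {
  wt <- wt_params()

  # no matter, no flux
  z <- ode_rhs("ternary", wt, species_state())
  expect_equal(unname(unlist(z)), rep(0, 6))

  # detailed-balance fixed point of the association step
  db <- ode_rhs("association", rate_params(k1 = 3.1, k_m1 = 5),
                species_state(P = 10, Dstar = 10, PDstar = 62))
  expect_equal(unname(db["PDstar"]), 3.1 * 10 * 10 - 5 * 62)
  expect_equal(unname(db["PDstar"]), 0)

  # hand-summed ternary flux: only the k2 step is live in this state
  d <- ode_rhs("ternary", update_rate_params(wt, k_m1 = 0),
               species_state(D = 1000, PDstar = 25))
  expect_equal(unname(d["T"]), 0.043 * 25 * 1000)   # 1075 nM/s
  expect_equal(unname(d["PDstar"]), -1075)

  # the derivative of every conserved total is exactly zero, all schemes
  set.seed(7)
  for (sc in schemes()) {
    for (i in 1:20) {
      st <- species_state(P = runif(1, 0, 50), Dstar = runif(1, 0, 50),
                          D = runif(1, 0, 4000), PDstar = runif(1, 0, 30),
                          PD = runif(1, 0, 30), T = runif(1, 0, 20))
      dv <- ode_rhs(sc, wt, st)
      expect_equal(unname(dv["P"] + dv["PDstar"] + dv["PD"] + dv["T"]), 0)
      expect_equal(unname(dv["Dstar"] + dv["PDstar"] + dv["T"]), 0)
      expect_equal(unname(dv["D"] + dv["PD"] + dv["T"]), 0)
    }
  }

  expect_error(ode_rhs("ternary", wt, c(P = -1, Dstar = 0, D = 0,
                                        PDstar = 0, PD = 0, T = 0)),
               "non-negative")
})

test_that("pre-equilibration solves the binding quadratic", {
  # stoichiometric limit
  s <- pre_equilibrate(37, 25, 3.1, 0)
  expect_equal(unname(s[c("PDstar", "P", "Dstar")]), c(25, 12, 0))
  # no protein
  s0 <- pre_equilibrate(0, 25, 3.1, 5)
  expect_equal(unname(s0[c("PDstar", "Dstar")]), c(0, 25))

  # K_D = 2 nM: check against an independent root-finder on the
  # equilibrium condition K_D * PDstar = (P0 - PDstar)(D0 - PDstar)
  kd <- 2
  oracle <- uniroot(function(x) (37 - x) * (25 - x) - kd * x,
                    c(0, 25), tol = 1e-12)$root
  got <- pre_equilibrate(37, 25, 3.1, 3.1 * kd)
  expect_equal(unname(got["PDstar"]), oracle, tolerance = 1e-9)
  expect_equal(unname(got["PDstar"]), 22.05, tolerance = 1e-4)

  # it is a fixed point of the association scheme
  dv <- ode_rhs("association", rate_params(k1 = 3.1, k_m1 = 3.1 * kd), got)
  expect_lt(max(abs(unlist(dv))), 1e-8)
  # and integrating the scheme to steady state lands on it
  traj <- simulate_trajectory("association", rate_params(k1 = 3.1,
                                                         k_m1 = 6.2),
                              species_state(P = 37, Dstar = 25),
                              c(0.001, 5))
  expect_equal(traj$PDstar[2], unname(got["PDstar"]), tolerance = 1e-6)

  expect_error(pre_equilibrate(37, 25, 0, 5), "k1 must be > 0")
})

test_that("equilibrium constants and per-site rescaling work", {
  expect_equal(kd_from_rates(0, 3.1), 0)
  # W589A: 20.2 / 4.2 rounds to 5 nM at one significant figure
  expect_equal(signif(kd_from_rates(20.2, 4.2), 1), 5)
  # WT second site: ratio of the fitted means (~2.4 uM)
  expect_equal(kd_from_rates(102, 0.043), 2372.093, tolerance = 1e-6)
  expect_error(kd_from_rates(5, 0), "k_on")

  expect_equal(per_site_rescale(0.12, 7, 7), 0.12)
  expect_equal(per_site_rescale(0.041, 450, 5), 3.69)
  expect_equal(per_site_rescale(3.69, 5, 450), 0.041)
  expect_error(per_site_rescale(1, 0, 5), "site counts")
})

test_that("the steady-state kobs formula behaves as an oracle should", {
  wt <- wt_params()
  expect_equal(approx_kobs_ternary(wt, 0), 0)
  expect_equal(approx_kobs_ternary(wt, 1e12), wt$k3, tolerance = 1e-6)

  # strictly increasing in competitor, bounded above by k3
  d <- 10^seq(0, 5, length.out = 60)
  k <- approx_kobs_ternary(wt, d)
  expect_true(all(diff(k) > 0))
  expect_true(all(k < wt$k3))

  # agrees with a full ODE simulation under its validity conditions
  # (negligible direct release, large competitor excess)
  p0 <- update_rate_params(wt, k_m1 = 0)
  init <- pre_equilibrate(37, 25, wt$k1, wt$k_m1)
  init["D"] <- 4000
  traj <- simulate_trajectory("ternary", p0, init,
                              exp(seq(log(0.0015), log(2),
                                      length.out = 300)))
  f <- fit_single_exponential(traj$time,
                              state_to_anisotropy(traj,
                                                  anisotropy_calibration(),
                                                  25))
  expect_lt(abs(f$kobs - approx_kobs_ternary(wt, 4000)) /
              approx_kobs_ternary(wt, 4000), 0.15)
})
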