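test_that("Arrhenius rates reproduce the canonical landscapes", {
  # identity landscape: all energies zero -> every rate equals the prefactor
  r0 <- rates_from_energies(energy_model(0, 0, 0, 0, 0))
  for (nm in paste0("k_", c("fc", "cf", "cb", "bc", "bf", "fb")))
    expect_equal(r0[[nm]], 1)

  # moderate affinity: E_c = 2 E_b = -10, barrierless downhill
  rm_ <- rates_from_energies(moderate_affinity_model())
  expect_equal(rm_$k_cb, exp(-5))
  expect_equal(rm_$k_cf, exp(-10))
  expect_equal(rm_$k_bc, 1)
  expect_equal(rm_$k_fc, 1)

  # high affinity: E_c = -150.5, E_b = T_cb = -150
  rh <- rates_from_energies(high_affinity_model())
  expect_equal(rh$k_cb, exp(-0.5))
  expect_equal(rh$k_bc, 1)
  expect_equal(rh$k_cf, exp(-150.5))

  # prefactor scales every rate
  r2 <- rates_from_energies(moderate_affinity_model(), prefactor = 3)
  expect_equal(r2$k_cb, 3 * rm_$k_cb)
})

test_that("unphysical landscapes are rejected with the inequality named", {
  expect_error(energy_model(E_c = -1, E_b = 0, T_fc = -2, T_cb = 0, T_bf = 0),
               "T_fc")
  expect_error(energy_model(E_c = -1, E_b = -3, T_cb = -5, T_fc = 0, T_bf = 0),
               "T_cb")
  expect_error(energy_model(E_c = -1, E_b = 2, T_bf = 1, T_fc = 0, T_cb = 2),
               "T_bf")
})

test_that("detailed balance holds for derived rates and flags broken sets", {
  set.seed(421)
  for (i in 1:100) {
    r <- rates_from_energies(random_energy_model(),
                             prefactor = runif(1, 0.1, 10))
    expect_lt(abs(detailed_balance_residual(r)), 1e-12)
  }
  r1 <- rates_from_energies(energy_model(0, 0, 0, 0, 0))
  expect_equal(detailed_balance_residual(r1), 0)
  r1$k_fc <- 2 * r1$k_fc
  expect_equal(detailed_balance_residual(r1), 1)
  r1$k_cf <- 0
  expect_error(detailed_balance_residual(r1), "zero")
})

test_that("closed-form occupancies match the explicit CTMC stationary solve", {
  set.seed(99)
  for (i in 1:100) {
    r <- rates_from_energies(random_energy_model())
    cG <- runif(1, 0.1, 5)
    cP <- runif(1, 0, 5)
    eq <- equilibrium_probabilities(r, cG, cP)
    pi_ <- stationary_distribution(r, cG, cP)
    expect_lt(abs(eq$P_free - pi_[["P_free"]]), 1e-10)
    expect_lt(abs(eq$P_crosslinked - pi_[["P_crosslinked"]]), 1e-10)
    expect_lt(abs(eq$P_bound - pi_[["P_bound"]]), 1e-10)
    expect_equal(eq$P_free + eq$P_crosslinked + eq$P_bound, 1)
  }
})

test_that("occupancies obey limits, monotonicity and rate-rescaling invariance", {
  r <- rates_from_energies(moderate_affinity_model())
  # no particles: two-state occupancy
  eq0 <- equilibrium_probabilities(r, c_eff_Gprime = 2, c_eff_P = 0)
  expect_equal(eq0$P_crosslinked, 2 * r$k_fc / (r$k_cf + 2 * r$k_fc))
  expect_equal(eq0$P_bound, 0)
  # P_crosslinked and tau both decrease with particle activity
  cp <- c(0, 0.5, 1, 2, 5)
  eq <- equilibrium_probabilities(r, 1, cp)
  expect_true(all(diff(eq$P_crosslinked) < 0))
  expect_true(all(diff(eq$tau_crosslinked) < 0))
  # rescaling all rates by a common factor leaves probabilities unchanged
  r3 <- rates_from_energies(moderate_affinity_model(), prefactor = 7.3)
  eq3 <- equilibrium_probabilities(r3, 1, cp)
  expect_equal(eq3$P_crosslinked, eq$P_crosslinked, tolerance = 1e-12)
  expect_equal(eq3$P_free, eq$P_free, tolerance = 1e-12)
})

test_that("crosslink lifetime follows 1 / (k_cf + c_P k_cb)", {
  r <- rates_from_energies(moderate_affinity_model())
  expect_equal(crosslink_lifetime(r, 0), 1 / r$k_cf)
  r2 <- r
  r2$k_cf <- 1; r2$k_cb <- 3
  expect_equal(crosslink_lifetime(r2, 2), 1 / 7)
  expect_error(crosslink_lifetime(list(k_cf = 0, k_cb = 0) |>
                                    structure(class = "rate_set"), 0),
               "exit")

  # Monte-Carlo first-exit oracle: exponential clocks on both channels
  r <- rates_from_energies(moderate_affinity_model(E_c = -3, E_b = -2))
  cP <- 1
  set.seed(7)
  n <- 1e5
  exit_times <- pmin(rexp(n, r$k_cf), rexp(n, cP * r$k_cb))
  mc <- mean(exit_times)
  se <- sd(exit_times) / sqrt(n)
  expect_lt(abs(mc - crosslink_lifetime(r, cP)), 3 * se)
})
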