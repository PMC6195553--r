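test_that("event enumeration follows the overlap-gated eligibility rules", {
  m <- moderate_affinity_model(E_c = -2, E_b = -1)
  r <- rates_from_energies(m)

  # isolated crosslinked overlapping pair -> exactly one cf event
  g <- frozen_triplet(crosslinked = TRUE, particle = FALSE)
  ev <- enumerate_events(g, r)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$type, "cf")
  expect_equal(ev$rate, r$k_cf)

  # crosslinked pair + binding particle overlapping the G end -> {cf, cb}
  g2 <- frozen_triplet(crosslinked = TRUE, particle = TRUE)
  ev2 <- enumerate_events(g2, r)
  expect_setequal(ev2$type, c("cf", "cb"))
  expect_equal(ev2$rate[ev2$type == "cb"], r$k_cb)
  expect_equal(ev2$partner[ev2$type == "cb"], 3L)

  # stretched crosslinked pair (s_ij > 0): no events at all
  g3 <- frozen_triplet(crosslinked = TRUE, particle = FALSE, stretch = TRUE)
  expect_equal(nrow(enumerate_events(g3, r)), 0L)

  # two overlapping free ends -> one fc event (unordered pair, no double count)
  g4 <- frozen_triplet(crosslinked = FALSE, particle = FALSE)
  ev4 <- enumerate_events(g4, r)
  expect_equal(nrow(ev4), 1L)
  expect_equal(ev4$type, "fc")

  # free end + overlapping binding particle -> fb; non-binding generates none
  g5 <- frozen_triplet(crosslinked = FALSE, particle = TRUE)
  ev5 <- enumerate_events(g5, r)
  expect_setequal(ev5$type, c("fc", "fb"))
  g6 <- g5
  g6$beads$binding <- FALSE
  expect_equal(nrow(enumerate_events(g6, r)), 1L)
})

test_that("a bound particle at capacity accepts no further bonds", {
  r <- rates_from_energies(moderate_affinity_model(E_c = -2, E_b = -1))
  g <- frozen_triplet(crosslinked = FALSE, particle = TRUE)
  g$sites$state[1] <- "bound"
  g$sites$partner[1] <- 3L
  # move the second end to overlap the particle too
  g$beads$ux[2] <- 3.8; g$beads$uy[2] <- 6.3
  g <- geldiff:::refresh_wrapped(g)
  ev <- enumerate_events(g, r)
  expect_false("fb" %in% ev$type)   # capacity 1 is exhausted
  # bf release of the bound site is eligible
  expect_true("bf" %in% ev$type)
})

test_that("advance_bonds leaves a gel without eligible events untouched", {
  g <- frozen_triplet(crosslinked = TRUE, particle = FALSE, stretch = TRUE)
  r <- rates_from_energies(moderate_affinity_model())
  sim <- advance_bonds(g, r, dt = 100, seed = 2)
  expect_equal(nrow(sim$events), 0L)
  expect_identical(sim$gel$sites$state, g$sites$state)
})

test_that("single-event firing probability matches the exponential clock", {
  # one crosslinked pair with only cf eligible at rate k; firing within dt
  # is Bernoulli(1 - exp(-k dt))
  m <- moderate_affinity_model(E_c = -1.2, E_b = -1)
  r <- rates_from_energies(m)
  g <- frozen_triplet(crosslinked = TRUE, particle = FALSE)
  dt <- 1.5
  p_expect <- 1 - exp(-r$k_cf * dt)
  n <- 800L
  fired <- vapply(seq_len(n), function(i) {
    sim <- advance_bonds(g, r, dt = dt, seed = 10000 + i)
    sim$event_counts[["cf"]] > 0
  }, logical(1))
  p_hat <- mean(fired)
  se <- sqrt(p_expect * (1 - p_expect) / n)
  expect_lt(abs(p_hat - p_expect), 3 * se)
})

test_that("frozen-geometry occupancies match the three-state equilibrium", {
  # the fixture realises the single-site chain with unit activities: the
  # particle overlaps only the first end, the complementary end is always
  # available
  m <- moderate_affinity_model(E_c = -2, E_b = -1, T_fc = 0.5, T_cb = 0.5,
                               T_bf = 0.5)
  r <- rates_from_energies(m)
  g <- frozen_triplet(crosslinked = FALSE, particle = TRUE)
  sim <- advance_bonds(g, r, dt = 20000, seed = 42)
  occ <- site_occupancy(sim, 1L)
  eq <- equilibrium_probabilities(r, c_eff_Gprime = 1, c_eff_P = 1)
  # block standard error from 20 sub-intervals
  blocks <- lapply(0:19, function(b) {
    ev <- sim$events[sim$events$time >= b * 1000 & sim$events$time < (b + 1) * 1000, ]
    ev
  })
  for (st in c("free", "crosslinked", "bound")) {
    frac <- occ$fraction[occ$state == st]
    expected <- switch(st, free = eq$P_free, crosslinked = eq$P_crosslinked,
                       bound = eq$P_bound)
    # conservative SE: occupancy correlation time ~ few units, 2e4 units total
    expect_lt(abs(frac - expected), 0.03)
  }
  expect_equal(sum(occ$fraction), 1, tolerance = 1e-9)
})

test_that("competitive binding holds along entire stochastic runs", {
  gel <- tiny_gel() |> place_particles(2, 0, seed = 6)
  m <- moderate_affinity_model(E_c = -3, E_b = -2)
  sim <- simulate_gel(gel, m, sim_config(steps = 3000, seed = 9))
  audit_gel(sim$gel, capacity = 1L)
  # direct exchange is atomic: after every cb the site is bound, never free
  rp <- geldiff:::replay_events(sim$sites_initial, sim$events, 0, sim$t_end)
  # completed intervals have positive duration (NA = censored at the start)
  expect_true(all(rp$intervals$lifetime > 0, na.rm = TRUE))
  # final state reconstructed from the log matches the engine state
  fs <- rp$final_state
  expect_identical(unname(fs[as.character(sim$gel$sites$bead)]),
                   sim$gel$sites$state)
})

test_that("bond count is conserved in the saturated high-affinity regime", {
  gel <- tiny_gel() |> place_particles(1, 0, seed = 2)
  n0 <- count_bonds(gel)
  m <- high_affinity_model()
  sim <- simulate_gel(gel, m, sim_config(steps = 5e4, seed = 13),
                      sample_every = 5e4)
  expect_identical(count_bonds(sim$gel), n0)
  # only the two atomic exchange channels ever fire
  expect_equal(sum(sim$event_counts[c("fc", "cf", "bf", "fb")]), 0)
})

test_that("exchange fluxes balance in a frozen two-site/particle system", {
  m <- moderate_affinity_model(E_c = -2, E_b = -1.5, T_fc = 0.5, T_cb = 0.5,
                               T_bf = 0.5)
  r <- rates_from_energies(m)
  g <- frozen_triplet(crosslinked = TRUE, particle = TRUE)
  sim <- advance_bonds(g, r, dt = 5000, seed = 17)
  n_cb <- sim$event_counts[["cb"]]
  n_bc <- sim$event_counts[["bc"]]
  expect_gt(n_cb, 50)
  # the site alternates c -> b -> c ... so the counts differ by at most one
  # per excursion through the free state; allow the statistical band
  expect_lt(abs(n_cb - n_bc), 3 * sqrt(n_cb) + 1)
})
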