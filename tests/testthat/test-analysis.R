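make_traj <- function(f, tmax = 100, dt = 1, d = 2) {
  tt <- seq(0, tmax, by = dt)
  out <- tibble::tibble(time = tt, bead = 1L, binding = FALSE)
  pos <- f(tt)
  out$ux <- pos[, 1]; out$uy <- pos[, 2]
  out
}

test_that("MSD reproduces closed forms for constant and ballistic motion", {
  const <- make_traj(function(t) cbind(rep(2, length(t)), rep(-1, length(t))))
  msd <- compute_msd(const)
  expect_true(all(msd$msd == 0))

  v <- 0.3
  ball <- make_traj(function(t) cbind(v * t, 0 * t))
  msd_b <- compute_msd(ball, lags = c(1, 5, 10, 20))
  expect_equal(msd_b$msd[-1], (v * msd_b$lag[-1])^2, tolerance = 1e-12)

  # lag beyond the span is refused
  expect_error(compute_msd(ball, lags = 1000), "lag exceeds")
})

test_that("diffusion estimation recovers the slope exactly and flags plateaus", {
  D <- 0.03
  tt <- seq(0, 100, by = 1)
  msd <- tibble::tibble(lag = tt, msd = 2 * 2 * D * tt, se = NA, n_series = 1)
  attr(msd, "d") <- 2L
  class(msd) <- c("msd_result", class(msd))
  fit <- estimate_diffusion(msd)
  expect_equal(fit$D, 0.03, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)

  # plateaued MSD: D consistent with zero, linearity diagnostic poor
  msd2 <- tibble::tibble(lag = tt, msd = 5 * (1 - exp(-tt / 2)), se = NA,
                         n_series = 1)
  attr(msd2, "d") <- 2L
  class(msd2) <- c("msd_result", class(msd2))
  fit2 <- estimate_diffusion(msd2, window = c(20, 100))
  expect_lt(fit2$D, 1e-3)
  expect_lt(fit2$r_squared, 0.98)
})

test_that("free Brownian particles recover the Einstein relation", {
  fit <- measure_free_diffusion(replicates = 60, steps = 1e4, seed = 314,
                                sample_every = 20)
  # statistical consistency at 3 SE, and honest accuracy at the 5% level
  expect_lt(abs(fit$D - D0_ANALYTIC_2D), 3 * fit$se + 0.05 * D0_ANALYTIC_2D)
  expect_gt(fit$r_squared, 0.99)
})

test_that("tidiers return the expected shapes", {
  fit <- measure_free_diffusion(replicates = 4, steps = 2e3, seed = 3)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("term", "estimate") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_true(all(c("D", "r.squared", "n_series") %in% names(gl)))
})

test_that("crosslink lifetimes are read off the event log", {
  # hand-built log: one crosslink formed at t=2 and broken at t=5
  sites <- tibble::tibble(bead = 1:2, state = "free", partner = NA_integer_,
                          active = TRUE)
  events <- tibble::tibble(time = c(2, 5), type = c("fc", "cf"),
                           site = 1L, partner = 2L, near = Inf)
  sim <- structure(list(sites_initial = sites, events = events,
                        t0 = 0, t_end = 10), class = "gel_sim")
  lt <- measure_crosslink_lifetime(sim)
  expect_equal(nrow(lt$intervals), 1L)
  expect_equal(lt$intervals$lifetime, 3)
  expect_equal(lt$summary$mean[lt$summary$group == "all"], 3)

  # intervals open at the start (saturation) or never closed are censored
  events2 <- tibble::tibble(time = 4, type = "fc", site = 1L, partner = 2L,
                            near = Inf)
  sim2 <- structure(list(sites_initial = sites, events = events2,
                         t0 = 0, t_end = 10), class = "gel_sim")
  expect_error(measure_crosslink_lifetime(sim2), "completed")
})

test_that("measured lifetimes follow 1/(k_cf + c_P k_cb) with overlap gating", {
  # shallow landscape so many full lifetimes fit in a short run
  m <- moderate_affinity_model(E_c = -3, E_b = -2)
  r <- rates_from_energies(m)
  # Breaking is gated on the pair overlapping, and in a thermalised lattice
  # gel the network prestress leaves crosslinked pairs overlapping only part
  # of the time, so the measured lifetime can only exceed the ungated 1/k_cf.
  gel <- build_gel(3L) |> saturate_crosslinks()
  cfg <- sim_config(steps = 4e5, seed = 21)
  sim <- simulate_gel(gel, m, cfg, sample_every = 4e4, track = "none")
  lt <- measure_crosslink_lifetime(sim)
  all_row <- lt$summary[lt$summary$group == "all", ]
  expect_gt(all_row$n, 100)
  expect_gt(all_row$mean, 1 / r$k_cf - 3 * all_row$se)

  # thermalised pairs overlap roughly half the time, so the gated lifetime
  # stays within a small factor of the ungated expectation
  expect_lt(all_row$mean, 4 / r$k_cf)
})

test_that("a nearby binding particle shortens the crosslink lifetime", {
  # frozen crosslinked pair: with an overlapping binding particle the exit
  # rate gains the direct-exchange channel, 1/(k_cf + k_cb) < 1/k_cf
  m <- moderate_affinity_model(E_c = -3, E_b = -2, T_fc = 0, T_cb = 0,
                               T_bf = 0)
  r <- rates_from_energies(m)
  sim_with <- advance_bonds(frozen_triplet(crosslinked = TRUE, particle = TRUE),
                            r, dt = 30000, seed = 31)
  sim_wo <- advance_bonds(frozen_triplet(crosslinked = TRUE, particle = FALSE),
                          r, dt = 30000, seed = 32)
  lt_with <- measure_crosslink_lifetime(sim_with)
  lt_wo <- measure_crosslink_lifetime(sim_wo)
  near <- lt_with$summary[lt_with$summary$group == "particle_near", ]
  wo <- lt_wo$summary[lt_wo$summary$group == "all", ]
  expect_gt(near$n, 50)
  # stratification: every interval of the frozen pair is particle-near
  expect_lt(near$mean + 3 * near$se, wo$mean)
  expect_lt(abs(near$mean - 1 / (r$k_cf + r$k_cb)), 3 * near$se)
  expect_lt(abs(wo$mean - 1 / r$k_cf), 3 * wo$se)
})

test_that("region counting classifies by wrapped radius", {
  traj <- tibble::tibble(
    time = c(0, 0, 1, 1), bead = c(1L, 2L, 1L, 2L),
    binding = c(TRUE, FALSE, TRUE, FALSE),
    ux = c(10, 11, 14, 11), uy = c(10, 10, 10, 10),
    x = c(10, 11, 14, 11), y = c(10, 10, 10, 10))
  sim <- structure(list(trajectory = traj, d = 2L, box = c(20, 20)),
                   class = "gel_sim")
  counts <- count_regions(sim, r_inner = 2, r_outer = 3.5)
  expect_equal(sum(counts$n), 4L)
  final <- counts[counts$time == 1, ]
  expect_equal(final$n[final$binding & final$region == "exterior"], 1L)
  expect_equal(final$n[!final$binding & final$region == "interior"], 1L)
})
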