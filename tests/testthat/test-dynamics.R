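test_that("pair potential has the two branches and is continuous at contact", {
  # contact: both branches give zero energy and force
  expect_equal(pair_energy(1, 0.5, 0.5, bonded = TRUE)$energy, 0)
  expect_equal(pair_energy(1, 0.5, 0.5, bonded = FALSE)$force, 0)
  # bonded, compressed by 0.1 at k_H = 400: V = 200 * 0.01 = 2
  expect_equal(pair_energy(0.9, 0.5, 0.5, bonded = TRUE)$energy, 2)
  # unbonded and separated: strictly zero
  e <- pair_energy(1.2, 0.5, 0.5, bonded = FALSE)
  expect_equal(e$energy, 0)
  expect_equal(e$force, 0)
  # unbonded but overlapping: repulsive
  expect_gt(pair_energy(0.8, 0.5, 0.5, bonded = FALSE)$force, 0)
  # bonded and stretched: attractive (negative radial force)
  expect_lt(pair_energy(1.2, 0.5, 0.5, bonded = TRUE)$force, 0)
})

test_that("bending energy is minimal for straight strands and forces balance", {
  # collinear: theta = pi, V = -k_BB
  be <- bend_energy(c(-1, 0), c(0, 0), c(1, 0))
  expect_equal(be$energy, -200)
  # right angle: V = -k_BB / 2
  be2 <- bend_energy(c(1, 0), c(0, 0), c(0, 1))
  expect_equal(be2$energy, -100)
  expect_error(bend_energy(c(0, 0), c(0, 0), c(1, 0)), "coincident")

  # forces: analytic gradient matches central finite differences, and the
  # triple feels no net force
  set.seed(12)
  for (i in 1:5) {
    p <- matrix(rnorm(6), 3, 2)
    be <- bend_energy(p[1, ], p[2, ], p[3, ])
    expect_equal(colSums(be$forces), c(0, 0), tolerance = 1e-10)
    h <- 1e-6
    for (bead in 1:3) for (k in 1:2) {
      pp <- p; pp[bead, k] <- pp[bead, k] + h
      pm <- p; pm[bead, k] <- pm[bead, k] - h
      fd <- -(bend_energy(pp[1, ], pp[2, ], pp[3, ])$energy -
                bend_energy(pm[1, ], pm[2, ], pm[3, ])$energy) / (2 * h)
      expect_equal(unname(be$forces[bead, k]), fd, tolerance = 1e-5)
    }
  }
})

test_that("friction follows gamma = 2 d pi eta R", {
  expect_equal(friction_coefficient(1, d = 2), 4 * pi)
  expect_equal(friction_coefficient(0.5, d = 2), 2 * pi)
  expect_equal(friction_coefficient(1, d = 3), 6 * pi)
  expect_equal(free_diffusion_constant(1, d = 2), 1 / (4 * pi))
})

test_that("engine forces are exact gradients and translation invariant", {
  gel <- tiny_gel() |> place_particles(1, 0, seed = 3)
  # perturb positions so nothing sits exactly at rest
  set.seed(31)
  n <- nrow(gel$beads)
  gel$beads$ux <- gel$beads$ux + rnorm(n, sd = 0.05)
  gel$beads$uy <- gel$beads$uy + rnorm(n, sd = 0.05)
  gel <- geldiff:::refresh_wrapped(gel)
  se <- system_energy(gel)
  # translation invariance: total force vanishes
  expect_equal(colSums(se$forces), c(0, 0), tolerance = 1e-8)
  # finite differences of the total energy reproduce the forces
  h <- 1e-6
  for (bead in c(1L, 5L, 9L, n)) for (k in 1:2) {
    gp <- gel; gm <- gel
    col <- c("ux", "uy")[k]
    gp$beads[[col]][bead] <- gp$beads[[col]][bead] + h
    gm$beads[[col]][bead] <- gm$beads[[col]][bead] - h
    fd <- -(system_energy(gp)$energy - system_energy(gm)$energy) / (2 * h)
    expect_equal(se$forces[bead, k], fd, tolerance = 1e-4)
  }
})

test_that("integrator reproduces its deterministic limits", {
  gel <- well_system()
  cfg <- sim_config(steps = 1)
  # zero force, no noise: nothing moves (bead 2 sits at the bond rest length)
  g1 <- integrate_step(gel, cfg, noise = FALSE)
  expect_equal(g1$beads$ux, gel$beads$ux)
  # constant external force: displacement F dt / gamma
  Fext <- matrix(0, 2, 2); Fext[2, 1] <- 10
  g2 <- integrate_step(gel, cfg, noise = FALSE, ext_force = Fext)
  gamma <- friction_coefficient(0.5, d = 2)
  expect_equal(g2$beads$ux[2] - gel$beads$ux[2], 10 * cfg$dt / gamma,
               tolerance = 1e-12)
  expect_equal(g2$beads$uy[2], gel$beads$uy[2])
  # an unstable step is caught
  Fbig <- matrix(0, 2, 2); Fbig[2, 1] <- 1e5
  expect_error(integrate_step(gel, cfg, noise = FALSE, ext_force = Fbig),
               "unstable")
})

test_that("thermal fluctuations in a harmonic bond satisfy equipartition", {
  # Euler-Maruyama carries an O(theta dt) bias in the stationary variance of
  # a stiff harmonic mode, so the check runs at a reduced time step where the
  # bias (~1.6% at dt = 5e-4) is well below the statistical resolution.
  gel <- well_system()
  sim <- simulate_gel(gel, NULL, sim_config(dt = 5e-4, steps = 6e5, seed = 7),
                      sample_every = 60, track = 2L)
  r <- sqrt((sim$trajectory$ux - 5)^2 + (sim$trajectory$uy - 5)^2)
  v <- var(r)
  n_eff <- length(r)
  se_rel <- sqrt(2 / n_eff)
  expect_lt(abs(v / (1 / 400) - 1), 3 * se_rel + 0.02)
})

test_that("identical seeds give bit-identical trajectories", {
  gel <- tiny_gel() |> place_particles(1, 0, seed = 4)
  m <- moderate_affinity_model()
  s1 <- simulate_gel(gel, m, sim_config(steps = 500, seed = 11))
  s2 <- simulate_gel(gel, m, sim_config(steps = 500, seed = 11))
  expect_identical(s1$trajectory, s2$trajectory)
  expect_identical(s1$events, s2$events)
  s3 <- simulate_gel(gel, m, sim_config(steps = 500, seed = 12))
  expect_false(identical(s1$trajectory, s3$trajectory))
})
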