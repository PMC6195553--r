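#' Simulation configuration
#'
#' Mechanical and numerical parameters of the overdamped Langevin / Gillespie
#' hybrid.  The defaults are the standard parameter set of the model: monomer
#' radius 0.5, particle radius 1, harmonic stiffness `k_H = 400`, bending
#' stiffness `k_BB = 200`, viscosity `eta = 1`, `kT = 1` and time step
#' `dt = 0.005` (all in reduced units with \eqn{k_B T = 1}).
#'
#' @param dt integration time step.
#' @param k_H harmonic pair stiffness (energy / length^2).
#' @param k_BB bond-bending stiffness (energy).
#' @param eta dynamic viscosity.
#' @param kT thermal energy (fixed to 1 in this model; energies are given in
#'   units of \eqn{k_B T}).
#' @param steps default number of BD steps per run.
#' @param seed default RNG seed.
#' @param prefactor attempt frequency \eqn{\omega_0} of the bond kinetics.
#' @param sample_every trajectory sampling stride (in steps).
#' @param capacity maximum concurrent particle-site bonds per particle.
#' @param max_step_disp per-step displacement bound; exceeding it aborts the
#'   run and signals an unstable `dt`/`k_H` combination.
#' @return A `sim_config` list.
#' @export
sim_config <- function(dt = 0.005, k_H = 400, k_BB = 200, eta = 1, kT = 1,
                       steps = 1e5, seed = 1L, prefactor = 1,
                       sample_every = 100L, capacity = 1L,
                       max_step_disp = 0.5) {
  stopifnot_scalar_number(dt, "dt", positive = TRUE)
  stopifnot_scalar_number(eta, "eta", positive = TRUE)
  stopifnot_scalar_number(kT, "kT", positive = TRUE)
  if (k_H < 0 || k_BB < 0) abort("`k_H` and `k_BB` must be >= 0")
  structure(list(dt = dt, k_H = k_H, k_BB = k_BB, eta = eta, kT = kT,
                 steps = steps, seed = seed, prefactor = prefactor,
                 sample_every = sample_every, capacity = as.integer(capacity),
                 max_step_disp = max_step_disp),
            class = "sim_config")
}

#' Friction coefficient and free diffusion constant
#'
#' The friction coefficient of a disk (sphere) of radius `R` is
#' \eqn{\gamma = 2 d \pi \eta R}; by the Einstein relation the corresponding
#' free diffusion constant is \eqn{D_0 = k_B T / \gamma}.
#'
#' @param R bead radius.
#' @param d spatial dimension.
#' @param eta dynamic viscosity.
#' @param kT thermal energy.
#' @return Friction coefficient (resp. diffusion constant), vectorized over
#'   `R`.
#' @examples
#' friction_coefficient(1, d = 2)      # 4 * pi
#' free_diffusion_constant(1, d = 2)   # 1 / (4 * pi)
#' @export
friction_coefficient <- function(R, d = 2, eta = 1) {
  if (any(R <= 0)) abort("`R` must be > 0")
  2 * d * pi * eta * R
}

#' @rdname friction_coefficient
#' @export
free_diffusion_constant <- function(R, d = 2, eta = 1, kT = 1) {
  kT / friction_coefficient(R, d = d, eta = eta)
}

#' Harmonic pair potential with a bond parameter
#'
#' Two disks at center distance `r_ij` with radii `R_i`, `R_j` interact
#' through \eqn{V = (k_H/2) s^2} with gap \eqn{s = r_{ij} - (R_i + R_j)}: a
#' two-sided harmonic bond when `bonded`, and a one-sided contact repulsion
#' (zero for non-overlapping disks) otherwise.  The two branches coincide for
#' \eqn{s \le 0}, so switching the bond parameter of an overlapping pair
#' leaves the energy continuous -- the property that lets the Gillespie
#' engine flip bonds without injecting energy.
#'
#' @param r_ij center-to-center distance(s).
#' @param R_i,R_j disk radii.
#' @param bonded logical: is there a bond (`b_ij = 1`)?
#' @param k_H stiffness.
#' @return A tibble with `r_ij`, `gap`, `energy` and the radial `force`
#'   \eqn{-dV/dr} (positive = repulsive).
#' @export
pair_energy <- function(r_ij, R_i = 0.5, R_j = 0.5, bonded = FALSE,
                        k_H = 400) {
  s <- r_ij - (R_i + R_j)
  act <- bonded | s <= 0
  tibble(
    r_ij = r_ij, gap = s,
    energy = ifelse(act, 0.5 * k_H * s^2, 0),
    force = ifelse(act, -k_H * s, 0)
  )
}

#' Bond-bending potential for three consecutive monomers
#'
#' For consecutive monomers `h`, `i`, `j` along one polymer strand the
#' bending energy is \eqn{V = (k_{BB}/2)(\cos\theta - 1)} where
#' \eqn{\theta} is the angle at the middle monomer.  The energy is minimal
#' (\eqn{-k_{BB}}) for a straight strand (\eqn{\theta = \pi}) and zero for a
#' fully folded one.  Forces are the exact negative gradient; they sum to
#' zero, so bending exerts no net force on the strand.
#'
#' @param p_h,p_i,p_j positions (numeric vectors of equal length).
#' @param k_BB bending stiffness.
#' @return List with `energy`, `theta`, and `forces` (rows `h`, `i`, `j`).
#' @export
bend_energy <- function(p_h, p_i, p_j, k_BB = 200) {
  a <- p_h - p_i
  b <- p_j - p_i
  la <- sqrt(sum(a^2)); lb <- sqrt(sum(b^2))
  if (la < 1e-12 || lb < 1e-12) abort("bond-bending: coincident monomers")
  cth <- sum(a * b) / (la * lb)
  ga <- b / (la * lb) - cth * a / la^2
  gb <- a / (la * lb) - cth * b / lb^2
  f_h <- -0.5 * k_BB * ga
  f_j <- -0.5 * k_BB * gb
  forces <- rbind(h = f_h, i = -(f_h + f_j), j = f_j)
  list(energy = 0.5 * k_BB * (cth - 1),
       theta = acos(max(-1, min(1, cth))),
       forces = forces)
}

# ---------------------------------------------------------------------------
# conversion between the R-side gel_system and the C++ engine state
# ---------------------------------------------------------------------------
as_engine <- function(gel, config) {
  b <- gel$beads
  n <- nrow(b)
  if (!identical(b$id, seq_len(n))) {
    # builders keep ids dense; re-normalise defensively
    map <- setNames(seq_len(n), b$id)
    b$id <- seq_len(n)
    gel$bonds$i <- unname(map[as.character(gel$bonds$i)])
    gel$bonds$j <- unname(map[as.character(gel$bonds$j)])
    for (cc in c("h", "i", "j"))
      gel$triples[[cc]] <- unname(map[as.character(gel$triples[[cc]])])
    gel$sites$bead <- unname(map[as.character(gel$sites$bead)])
    ok <- !is.na(gel$sites$partner)
    gel$sites$partner[ok] <- unname(map[as.character(gel$sites$partner[ok])])
    gel$beads <- b
  }
  d <- gel$d
  state <- rep(-2L, n)
  partner <- rep(-1L, n)
  codes <- c(free = 0L, crosslinked = 1L, bound = 2L)
  s <- gel$sites
  state[s$bead] <- ifelse(s$active, codes[s$state], -1L)
  partner[s$bead[!is.na(s$partner)]] <- s$partner[!is.na(s$partner)] - 1L
  species <- rep(-1L, n)
  if ("species" %in% names(s)) {
    sp <- ifelse(is.na(s$species), -1L, ifelse(s$species == "G", 0L, 1L))
    species[s$bead] <- sp
  }
  list(
    ux = as.matrix(gel$beads[, upos_cols(d)]),
    radius = gel$beads$radius,
    role = match(gel$beads$role, .ROLES) - 1L,
    binding = as.integer(gel$beads$binding),
    mobile = as.integer(gel$beads$mobile),
    site_state = as.integer(state),
    partner = as.integer(partner),
    species = as.integer(species),
    perm_bonds = matrix(as.integer(c(gel$bonds$i, gel$bonds$j) - 1L),
                        ncol = 2),
    triples = matrix(as.integer(
      c(gel$triples$h, gel$triples$i, gel$triples$j) - 1L), ncol = 3),
    box = gel$box,
    params = list(dt = config$dt, k_H = config$k_H, k_BB = config$k_BB,
                  eta = config$eta, kT = config$kT,
                  capacity = config$capacity),
    gel = gel
  )
}

from_engine <- function(gel, res) {
  d <- gel$d
  for (k in seq_len(d)) gel$beads[[upos_cols(d)[k]]] <- res$ux[, k]
  st <- res$site_state[gel$sites$bead]
  pt <- res$partner[gel$sites$bead]
  lab <- c("free", "crosslinked", "bound")
  upd <- st >= 0L
  gel$sites$state[upd] <- lab[st[upd] + 1L]
  gel$sites$partner <- ifelse(pt >= 0L, pt + 1L, NA_integer_)
  refresh_wrapped(gel)
}

engine_events_tibble <- function(ev) {
  tibble(
    time = as.numeric(ev$time),
    type = .TRANSITIONS[as.integer(ev$type) + 1L],
    site = as.integer(ev$site) + 1L,
    partner = as.integer(ev$partner) + 1L,
    near = as.numeric(ev$near)
  )
}

#' Advance the system by Brownian-dynamics / Gillespie steps
#'
#' Runs the hybrid simulation: each fixed time step `dt` advances every
#' mobile bead by an Euler--Maruyama update of the overdamped Langevin
#' equation (drift \eqn{F/\gamma} plus Gaussian noise of per-coordinate
#' variance \eqn{2 k_B T \Delta t / \gamma}), and between consecutive BD
#' steps the bond topology evolves by a Gillespie simulation of the eligible
#' transitions that terminates at \eqn{\Delta t}.  Bond changes are gated on
#' disk overlap, so the total energy is continuous across every event.
#'
#' @param gel a `gel_system`.
#' @param rates a `rate_set` (or `energy_model`); `NULL` disables the bond
#'   kinetics.
#' @param config a [sim_config()].
#' @param steps number of BD steps.
#' @param seed RNG seed for this run (the engine RNG is deterministic given
#'   the seed).
#' @param sample_every trajectory sampling stride, in steps.
#' @param noise set `FALSE` to suppress thermal noise (deterministic drift;
#'   for testing).
#' @param track which beads to record: `"particles"`, `"ends"` (particles
#'   plus strand ends), `"all"`, or an integer vector of bead ids.
#' @param ext_force optional `n x d` matrix of constant external forces.
#' @param record_events keep the individual bond-event log (disable for very
#'   long runs where only counts matter).
#' @param t0 simulation time at the start of the run.
#' @return A `gel_sim` object: final `gel`, tibbles `trajectory` (unwrapped
#'   and wrapped tracked coordinates per frame) and `events`, named
#'   `event_counts`, and run metadata.
#' @examples
#' gel <- build_gel(2) |> saturate_crosslinks() |> place_particles(seed = 1)
#' sim <- simulate_gel(gel, moderate_affinity_model(),
#'                     sim_config(steps = 200, seed = 1))
#' sim$trajectory
#' @export
simulate_gel <- function(gel, rates = NULL, config = sim_config(),
                         steps = config$steps, seed = config$seed,
                         sample_every = config$sample_every, noise = TRUE,
                         track = "particles", ext_force = NULL,
                         record_events = TRUE, t0 = 0) {
  stopifnot(inherits(gel, "gel_system"))
  st <- as_engine(gel, config)
  gel <- st$gel
  do_g <- !is.null(rates)
  rv <- if (do_g) as_rate_vector(rates) else numeric(6)
  track_ids <- resolve_track(gel, track)
  res <- cpp_run(st$ux, st$radius, st$role, st$binding, st$mobile,
                 st$site_state, st$partner, st$species, st$perm_bonds,
                 st$triples, st$box, st$params, rv, as.double(steps),
                 as.double(sample_every), as.double(seed),
                 TRUE, do_g, noise, config$dt, as.integer(track_ids - 1L),
                 ext_force, record_events, t0, config$max_step_disp)
  build_gel_sim(gel, res, track_ids, config, rates, seed, t0,
                kinetics_only = FALSE)
}

resolve_track <- function(gel, track) {
  b <- gel$beads
  if (is.numeric(track)) return(as.integer(track))
  switch(track,
    particles = b$id[b$role == "particle"],
    ends = b$id[b$role %in% c("end", "particle")],
    all = b$id,
    none = integer(0),
    abort("unknown `track` option")
  )
}

build_gel_sim <- function(gel, res, track_ids, config, rates, seed, t0,
                          kinetics_only) {
  d <- gel$d
  sites_initial <- gel$sites
  out_gel <- from_engine(gel, res)
  ntrk <- length(track_ids)
  nframes <- length(res$times)
  traj <- NULL
  if (ntrk > 0) {
    m <- res$traj
    traj <- vector("list", ntrk)
    for (q in seq_len(ntrk)) {
      cols <- (q - 1L) * d + seq_len(d)
      tt <- tibble(time = res$times,
                   bead = rep(track_ids[q], nframes),
                   binding = gel$beads$binding[track_ids[q]])
      for (k in seq_len(d)) tt[[upos_cols(d)[k]]] <- m[, cols[k]]
      for (k in seq_len(d))
        tt[[pos_cols(d)[k]]] <- wrap_coord(m[, cols[k]], gel$box[k])
      # gel network COM displacement, for drift-free relative MSDs
      for (k in seq_len(d))
        tt[[paste0("g", pos_cols(d)[k])]] <- res$com[, k]
      traj[[q]] <- tt
    }
    traj <- bind_rows(traj)
  } else {
    traj <- tibble(time = numeric(0), bead = integer(0),
                   binding = logical(0))
  }
  structure(list(
    gel = out_gel,
    sites_initial = sites_initial,
    trajectory = traj,
    events = engine_events_tibble(res$events),
    event_counts = setNames(as.numeric(res$event_counts), .TRANSITIONS),
    config = config, rates = rates, seed = seed,
    t0 = t0, t_end = res$t_end, d = d, box = gel$box,
    kinetics_only = kinetics_only
  ), class = "gel_sim")
}

#' @export
print.gel_sim <- function(x, ...) {
  cat(sprintf("<gel_sim> %dD, t = [%g, %g], %d tracked bead(s), %d event(s)\n",
              x$d, x$t0, x$t_end, length(unique(x$trajectory$bead)),
              nrow(x$events)))
  cat("  events:", paste(sprintf("%s=%d", names(x$event_counts),
                                 x$event_counts), collapse = " "), "\n")
  invisible(x)
}

#' Single Euler--Maruyama step
#'
#' Advances the mechanical degrees of freedom by one time step without any
#' bond kinetics; mostly useful for testing the integrator against its
#' closed-form limits (zero-force invariance, deterministic drift
#' \eqn{F \Delta t / \gamma}, equipartition in a harmonic bond).
#'
#' @inheritParams simulate_gel
#' @return The updated `gel_system`.
#' @export
integrate_step <- function(gel, config = sim_config(), noise = TRUE,
                           seed = config$seed, ext_force = NULL) {
  sim <- simulate_gel(gel, rates = NULL, config = config, steps = 1,
                      seed = seed, sample_every = 1, noise = noise,
                      track = "none", ext_force = ext_force,
                      record_events = FALSE)
  sim$gel
}

#' Total potential energy and exact forces
#'
#' Evaluates the full interaction energy (pair + bending) of the current
#' configuration and its exact negative gradient, as used by the integrator.
#'
#' @param gel a `gel_system`.
#' @param config a [sim_config()].
#' @return List with `energy` and the `n x d` matrix `forces`.
#' @export
system_energy <- function(gel, config = sim_config()) {
  st <- as_engine(gel, config)
  res <- cpp_forces(st$ux, st$radius, st$role, st$binding, st$mobile,
                    st$site_state, st$partner, st$species, st$perm_bonds,
                    st$triples, st$box, st$params, numeric(6))
  list(energy = res$energy, forces = res$forces)
}
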