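#' Enumerate the eligible stochastic bond transitions
#'
#' Lists every transition of the three-state site model that is currently
#' eligible, given the bead positions and site states.  A bond may only
#' change while the two disks involved overlap (\eqn{s_{ij} < 0}); the two
#' exchange transitions additionally require the bond being broken to be
#' overlapping, so that every executed event leaves the total energy
#' continuous.  Eligible channels:
#'
#' * `fc` -- two overlapping free strand ends (one event per unordered pair);
#' * `cf` -- a crosslinked pair, currently overlapping;
#' * `cb` -- a crosslinked site overlapped by a binding particle with spare
#'   capacity; executes atomically as break-GG' / form-GP (the partner end
#'   becomes free, never passing the site through the free state);
#' * `bc` -- a bound site overlapped by a free end; executes atomically as
#'   break-GP / form-GG' (the particle is released);
#' * `bf` -- a bound site-particle pair, currently overlapping;
#' * `fb` -- a free site overlapped by a binding particle with capacity.
#'
#' Non-binding particles generate no events.
#'
#' @param gel a `gel_system`.
#' @param rates a `rate_set` (or `energy_model`).
#' @param config a [sim_config()] (supplies the particle capacity).
#' @return A tibble with one row per eligible event: `site`, `type`,
#'   `partner`, `rate`.
#' @export
enumerate_events <- function(gel, rates, config = sim_config()) {
  stopifnot(inherits(gel, "gel_system"))
  st <- as_engine(gel, config)
  rv <- as_rate_vector(rates)
  ev <- cpp_enumerate(st$ux, st$radius, st$role, st$binding, st$mobile,
                      st$site_state, st$partner, st$species, st$perm_bonds,
                      st$triples, st$box, st$params, rv)
  tibble(
    site = ev$site + 1L,
    type = .TRANSITIONS[ev$type + 1L],
    partner = ev$partner + 1L,
    rate = ev$rate
  )
}

#' Advance the bond topology at frozen positions
#'
#' Runs the Gillespie algorithm over one interval of length `dt` with all
#' bead positions frozen: waiting times are exponential in the total rate,
#' events are picked proportionally to their rates, and the eligible-event
#' list is rebuilt after every execution (states change, positions do not).
#' This is exactly the kinetics half of one hybrid step, exposed separately
#' so the stochastic engine can be validated against the closed-form
#' three-state equilibrium.
#'
#' @inheritParams enumerate_events
#' @param dt interval length (need not equal the BD time step).
#' @param seed RNG seed.
#' @param t0 absolute time of the interval start (stamps the event log).
#' @return A `gel_sim` with the updated gel and the event log; positions are
#'   untouched.
#' @export
advance_bonds <- function(gel, rates, dt, config = sim_config(),
                          seed = config$seed, t0 = 0) {
  stopifnot(inherits(gel, "gel_system"))
  st <- as_engine(gel, config)
  gel <- st$gel
  rv <- as_rate_vector(rates)
  res <- cpp_run(st$ux, st$radius, st$role, st$binding, st$mobile,
                 st$site_state, st$partner, st$species, st$perm_bonds,
                 st$triples, st$box, st$params, rv, 1, 1, as.double(seed),
                 FALSE, TRUE, FALSE, dt, integer(0), NULL, TRUE, t0,
                 config$max_step_disp)
  build_gel_sim(gel, res, integer(0), config, rates, seed, t0,
                kinetics_only = TRUE)
}

#' Total dynamic bond count
#'
#' Number of crosslinks plus particle bonds.  In the high-affinity saturated
#' regime (spontaneous breaking suppressed) this count is exactly conserved:
#' the only accessible transitions are the two atomic exchanges, each of
#' which breaks one bond and forms another.
#'
#' @param gel a `gel_system`.
#' @return Integer bond count.
#' @export
count_bonds <- function(gel) {
  s <- gel$sites
  n_cross <- sum(s$state == "crosslinked") / 2
  n_gp <- sum(s$state == "bound")
  as.integer(n_cross + n_gp)
}
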