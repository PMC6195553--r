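#' Three-state energy landscape for a crosslink binding site
#'
#' A crosslink binding site on a strand end can be *free*, *crosslinked* (to a
#' complementary strand end) or *bound* (to a binding particle).  The kinetics
#' of the three-state cycle are fully specified by two state energies and
#' three transition-state energies, all in units of \eqn{k_B T}; the free
#' state defines the energy zero.  Transition-state energies must be at least
#' as large as both adjoining state energies, otherwise the Arrhenius rates
#' would exceed the attempt frequency and the landscape is unphysical.
#'
#' @param E_c energy of the crosslinked state (units \eqn{k_B T}).
#' @param E_b energy of the particle-bound state.
#' @param T_fc transition-state energy between free and crosslinked.
#' @param T_cb transition-state energy between crosslinked and bound.
#' @param T_bf transition-state energy between bound and free.
#' @return An object of class `energy_model`.
#' @seealso [rates_from_energies()], [high_affinity_model()],
#'   [moderate_affinity_model()]
#' @examples
#' energy_model(E_c = -10, E_b = -5, T_fc = 0, T_cb = -5, T_bf = 0)
#' @export
energy_model <- function(E_c, E_b, T_fc, T_cb, T_bf) {
  for (nm in c("E_c", "E_b", "T_fc", "T_cb", "T_bf"))
    stopifnot_scalar_number(get(nm), nm)
  tol <- 1e-12
  if (T_fc < max(0, E_c) - tol)
    abort("unphysical landscape: requires T_fc >= max(E_f = 0, E_c)")
  if (T_cb < max(E_c, E_b) - tol)
    abort("unphysical landscape: requires T_cb >= max(E_c, E_b)")
  if (T_bf < max(E_b, 0) - tol)
    abort("unphysical landscape: requires T_bf >= max(E_b, E_f = 0)")
  structure(list(E_c = E_c, E_b = E_b, T_fc = T_fc, T_cb = T_cb, T_bf = T_bf),
            class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat("<energy_model> (units k_B T; E_f = 0)\n")
  cat(sprintf("  states:      E_c = %g, E_b = %g\n", x$E_c, x$E_b))
  cat(sprintf("  transitions: T_fc = %g, T_cb = %g, T_bf = %g\n",
              x$T_fc, x$T_cb, x$T_bf))
  invisible(x)
}

#' Canonical high-affinity landscape
#'
#' Deeply bound crosslinked and particle-bound states with a small barrier
#' between them, while the barriers to the free state stay at zero energy, so
#' spontaneous crosslink breaking is suppressed by a factor
#' \eqn{e^{-depth}}.  With the defaults the landscape is
#' \eqn{E_c = -150.5}, \eqn{E_b = T_{cb} = -150}, \eqn{T_{fc} = T_{bf} = 0}:
#' crosslinked and bound states exchange easily but neither can reach the
#' free state, which is the regime of perfect filtering.
#'
#' @param delta_E difference `E_b - E_c` between bound and crosslinked state
#'   energies.
#' @param delta_T barrier height `T_cb - max(E_c, E_b)` for the direct
#'   exchange transition.
#' @param depth magnitude of the crosslinked-state energy `-E_c`.
#' @return An `energy_model`.
#' @export
high_affinity_model <- function(delta_E = 0.5, delta_T = 0, depth = 150.5) {
  E_c <- -depth
  E_b <- E_c + delta_E
  energy_model(E_c = E_c, E_b = E_b, T_fc = 0,
               T_cb = max(E_c, E_b) + delta_T, T_bf = 0)
}

#' Canonical moderate-affinity landscape
#'
#' All barriers are a few \eqn{k_B T}, so every transition of the three-state
#' cycle is accessible and crosslinks spontaneously break and reform: the gel
#' is reversible and self-healing.  The default sets \eqn{E_c = 2 E_b = -10}
#' with every transition-state energy equal to the larger of its two
#' adjoining state energies, the regime in which particle binding enhances
#' tracer diffusion roughly fivefold in two dimensions.
#'
#' @param E_c crosslinked-state energy (units \eqn{k_B T}).
#' @param E_b bound-state energy.
#' @param T_fc,T_cb,T_bf optional transition-state energies; by default each
#'   equals the larger of its adjoining state energies (barrierless in the
#'   downhill direction).
#' @return An `energy_model`.
#' @export
moderate_affinity_model <- function(E_c = -10, E_b = -5,
                                    T_fc = max(0, E_c),
                                    T_cb = max(E_c, E_b),
                                    T_bf = max(E_b, 0)) {
  energy_model(E_c = E_c, E_b = E_b, T_fc = T_fc, T_cb = T_cb, T_bf = T_bf)
}

#' Arrhenius transition rates from an energy landscape
#'
#' Each of the six rates of the three-state cycle is
#' \eqn{k_{\mu\nu} = \omega_0 \exp(-(T_{\mu\nu} - E_\mu))} with
#' \eqn{k_B T = 1}, where \eqn{\omega_0} is the attempt frequency that sets
#' the overall bond-kinetics time scale.  Rates constructed this way satisfy
#' detailed balance around the cycle,
#' \eqn{k_{fc} k_{cb} k_{bf} = k_{fb} k_{bc} k_{cf}}.
#'
#' @param model an [energy_model()].
#' @param prefactor attempt frequency \eqn{\omega_0} (inverse simulation time
#'   units).
#' @return An object of class `rate_set`: the six rates `k_fc`, `k_cf`,
#'   `k_cb`, `k_bc`, `k_bf`, `k_fb` plus the prefactor.
#' @examples
#' rates_from_energies(moderate_affinity_model())
#' @export
rates_from_energies <- function(model, prefactor = 1) {
  if (!inherits(model, "energy_model"))
    model <- do.call(energy_model, as.list(model))
  stopifnot_scalar_number(prefactor, "prefactor", positive = TRUE)
  E_f <- 0
  r <- list(
    k_fc = prefactor * exp(-(model$T_fc - E_f)),
    k_cf = prefactor * exp(-(model$T_fc - model$E_c)),
    k_cb = prefactor * exp(-(model$T_cb - model$E_c)),
    k_bc = prefactor * exp(-(model$T_cb - model$E_b)),
    k_bf = prefactor * exp(-(model$T_bf - model$E_b)),
    k_fb = prefactor * exp(-(model$T_bf - E_f)),
    prefactor = prefactor
  )
  structure(r, class = "rate_set")
}

#' @export
print.rate_set <- function(x, ...) {
  cat("<rate_set> (attempt frequency", format(x$prefactor), ")\n")
  for (nm in paste0("k_", .TRANSITIONS))
    cat(sprintf("  %s = %.6g\n", nm, x[[nm]]))
  invisible(x)
}

as_rate_vector <- function(rates) {
  if (inherits(rates, "energy_model")) rates <- rates_from_energies(rates)
  vapply(paste0("k_", .TRANSITIONS), function(nm) rates[[nm]], numeric(1))
}

#' Detailed-balance residual of a rate set
#'
#' Returns \eqn{k_{fc} k_{cb} k_{bf} / (k_{fb} k_{bc} k_{cf}) - 1}, which is
#' zero (to rounding) for any rate set derived from an energy landscape.  A
#' nonzero residual signals a rate set that would pump probability around the
#' free/crosslinked/bound cycle.
#'
#' @param rates a `rate_set`.
#' @return A dimensionless residual.
#' @export
detailed_balance_residual <- function(rates) {
  den <- rates$k_fb * rates$k_bc * rates$k_cf
  if (den == 0)
    abort("detailed-balance check needs all six rates > 0 (zero in cycle)")
  rates$k_fc * rates$k_cb * rates$k_bf / den - 1
}

#' Equilibrium state occupancies of a crosslink binding site
#'
#' Closed-form equilibrium probabilities of a single binding site being
#' free, crosslinked or particle-bound, given the transition rates and the
#' local effective concentrations (dimensionless activities) of complementary
#' binding sites (`c_eff_Gprime`) and binding particles (`c_eff_P`) in its
#' vicinity:
#' \deqn{P_{cross} = \frac{c_{G'} k_{fc}}{k_{cf} + c_{G'} k_{fc} +
#'   c_P k_{cf} k_{fb} / k_{bf}}}
#' with \eqn{P_{free}} sharing the same denominator (numerator
#' \eqn{k_{cf}}) and \eqn{P_{bound} = 1 - P_{free} - P_{cross}}.  A nearby
#' binding particle (\eqn{c_P > 0}) lowers both the crosslinked and the free
#' occupancy.  These closed forms equal the stationary distribution of the
#' three-state Markov jump process whose bimolecular channels are weighted by
#' the activities, and serve as the analytic oracle for the stochastic
#' engine.
#'
#' @param rates a `rate_set` (or `energy_model`, converted with unit
#'   prefactor).
#' @param c_eff_Gprime,c_eff_P non-negative activities; vectors are recycled
#'   to a common length.
#' @return A tibble with one row per activity combination: `c_eff_Gprime`,
#'   `c_eff_P`, `P_free`, `P_crosslinked`, `P_bound`, `tau_crosslinked`.
#' @examples
#' equilibrium_probabilities(moderate_affinity_model(), c_eff_P = c(0, 1))
#' @export
equilibrium_probabilities <- function(rates, c_eff_Gprime = 1, c_eff_P = 0) {
  if (inherits(rates, "energy_model")) rates <- rates_from_energies(rates)
  if (any(c_eff_Gprime < 0) || any(c_eff_P < 0))
    abort("activities must be non-negative")
  if (rates$k_bf == 0 && any(c_eff_P > 0))
    abort("k_bf = 0 with c_eff_P > 0: bound state would be absorbing")
  nn <- max(length(c_eff_Gprime), length(c_eff_P))
  cG <- rep_len(c_eff_Gprime, nn)
  cP <- rep_len(c_eff_P, nn)
  bound_term <- if (rates$k_bf > 0) cP * rates$k_cf * rates$k_fb / rates$k_bf
                else rep(0, nn)
  den <- rates$k_cf + cG * rates$k_fc + bound_term
  tibble(
    c_eff_Gprime = cG,
    c_eff_P = cP,
    P_free = rates$k_cf / den,
    P_crosslinked = cG * rates$k_fc / den,
    P_bound = bound_term / den,
    tau_crosslinked = crosslink_lifetime(rates, cP)
  )
}

#' Mean lifetime of the crosslinked state
#'
#' The crosslinked state has two exit channels: spontaneous breaking (rate
#' \eqn{k_{cf}}) and direct exchange to a nearby binding particle (rate
#' \eqn{c_P k_{cb}}), giving
#' \eqn{\tau_{cross} = 1 / (k_{cf} + c_P k_{cb})}.  The lifetime strictly
#' decreases with the particle activity whenever \eqn{k_{cb} > 0}: binding
#' particles accelerate crosslink turnover without changing the equilibrium
#' bond count.
#'
#' @inheritParams equilibrium_probabilities
#' @return Lifetime(s) in simulation time units.
#' @export
crosslink_lifetime <- function(rates, c_eff_P = 0) {
  if (inherits(rates, "energy_model")) rates <- rates_from_energies(rates)
  if (any(c_eff_P < 0)) abort("activities must be non-negative")
  den <- rates$k_cf + c_eff_P * rates$k_cb
  if (any(den <= 0))
    abort("crosslinked state has no open exit channel (zero total exit rate)")
  1 / den
}

#' Stationary distribution of the explicit three-state jump process
#'
#' Independent cross-check for [equilibrium_probabilities()]: builds the
#' generator of the continuous-time Markov chain over (free, crosslinked,
#' bound) with the bimolecular channels weighted by the activities
#' (`c_eff_Gprime` on the two crosslink-forming transitions, `c_eff_P` on the
#' two particle-binding transitions) and solves for its stationary
#' distribution as a linear system.
#'
#' @inheritParams equilibrium_probabilities
#' @return Named numeric vector `c(P_free, P_crosslinked, P_bound)`.
#' @export
stationary_distribution <- function(rates, c_eff_Gprime = 1, c_eff_P = 0) {
  if (inherits(rates, "energy_model")) rates <- rates_from_energies(rates)
  Q <- matrix(0, 3, 3,
              dimnames = list(c("f", "c", "b"), c("f", "c", "b")))
  Q["f", "c"] <- c_eff_Gprime * rates$k_fc
  Q["c", "f"] <- rates$k_cf
  Q["c", "b"] <- c_eff_P * rates$k_cb
  Q["b", "c"] <- c_eff_Gprime * rates$k_bc
  Q["b", "f"] <- rates$k_bf
  Q["f", "b"] <- c_eff_P * rates$k_fb
  diag(Q) <- -rowSums(Q)
  A <- rbind(t(Q), rep(1, 3))
  pi_ <- qr.solve(A, c(0, 0, 0, 1))
  setNames(pi_, c("P_free", "P_crosslinked", "P_bound"))
}
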