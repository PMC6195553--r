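# Small fixtures shared across test files.  Everything is generated in code;
# heavier shared simulations live in helper-sims.R and are memoised.

# a 2x2 lattice gel (36 beads, 16 end sites)
tiny_gel <- function(saturated = TRUE) {
  g <- build_gel(2L, d = 2L)
  if (saturated) g <- saturate_crosslinks(g)
  g
}

# one mobile bead bonded to a frozen anchor: a radial harmonic well
well_system <- function() {
  gel <- geldiff:::empty_system(2, 20)
  gel$beads <- tibble::tibble(
    id = 1:2, star = NA_integer_, role = c("end", "end"), binding = FALSE,
    radius = 0.5, mobile = c(FALSE, TRUE), ux = c(5, 6), uy = c(5, 5))
  gel$bonds <- tibble::tibble(i = 1L, j = 2L)
  gel$sites <- tibble::tibble(bead = 1:2, state = "free",
                              partner = NA_integer_, active = FALSE)
  geldiff:::refresh_wrapped(gel)
}

# frozen pair of complementary ends plus one binding particle that overlaps
# only the first end: realises the single-site three-state chain with unit
# activities
frozen_triplet <- function(crosslinked = FALSE, particle = TRUE,
                           stretch = FALSE) {
  gel <- geldiff:::empty_system(2, 20)
  n <- if (particle) 3L else 2L
  gel$beads <- tibble::tibble(
    id = seq_len(n), star = NA_integer_,
    role = c("end", "end", "particle")[seq_len(n)],
    binding = c(FALSE, FALSE, TRUE)[seq_len(n)],
    radius = c(0.5, 0.5, 1)[seq_len(n)], mobile = FALSE,
    ux = c(5, if (stretch) 6.2 else 5.9, 3.8)[seq_len(n)],
    uy = rep(5, n))
  gel$sites <- tibble::tibble(bead = 1:2,
                              state = if (crosslinked) "crosslinked" else "free",
                              partner = if (crosslinked) c(2L, 1L)
                                        else NA_integer_,
                              active = TRUE)
  geldiff:::refresh_wrapped(gel)
}

# random physical energy landscape (transition states above both neighbours)
random_energy_model <- function() {
  E_c <- runif(1, -6, 2)
  E_b <- runif(1, -6, 2)
  energy_model(E_c = E_c, E_b = E_b,
               T_fc = max(0, E_c) + runif(1, 0, 3),
               T_cb = max(E_c, E_b) + runif(1, 0, 3),
               T_bf = max(E_b, 0) + runif(1, 0, 3))
}

D0_ANALYTIC_2D <- 1 / (4 * pi)
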