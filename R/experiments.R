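# Higher-level experiment drivers: these are the pipelines behind the
# headline results (perfect filtering, the high-affinity sweep, the shell
# filter, moderate-affinity enhancement).

empty_system <- function(d = 2L, L = 50) {
  beads <- tibble(id = integer(0), star = integer(0), role = character(0),
                  arm = integer(0), binding = logical(0),
                  radius = numeric(0), mobile = logical(0))
  for (k in seq_len(d)) beads[[upos_cols(d)[k]]] <- numeric(0)
  gel <- structure(list(
    beads = beads,
    bonds = tibble(i = integer(0), j = integer(0)),
    sites = tibble(bead = integer(0), state = character(0),
                   partner = integer(0), active = logical(0)),
    triples = tibble(h = integer(0), i = integer(0), j = integer(0)),
    box = rep(L, d), d = as.integer(d), a = NA_real_, spacing = NA_real_,
    R_m = NA_real_, meta = list()
  ), class = "gel_system")
  refresh_wrapped(gel)
}

#' Measure the free-particle diffusion constant
#'
#' Simulates independent tracer particles in an empty periodic box and fits
#' the MSD slope, recovering \eqn{D_0 = k_B T / (2 d \pi \eta R_p)}.  The
#' measured value (rather than the analytic one) is used as the reference
#' when reporting \eqn{D/D_0} of gel runs, so discretisation error cancels;
#' the analytic value serves as a cross-check.
#'
#' @param d spatial dimension.
#' @param R_p particle radius.
#' @param replicates number of independent particles.
#' @param steps BD steps per replicate.
#' @param box_size box edge length.
#' @param config a [sim_config()].
#' @param sample_every sampling stride.
#' @param seed RNG seed.
#' @param window_frac fit window as a fraction of the maximum lag; short
#'   lags are used because time-averaged MSD estimates lose precision at
#'   lags comparable to the run length while a free particle is diffusive
#'   at every lag.
#' @return A `diffusion_fit`; element `D` is the measured \eqn{D_0}.
#' @export
measure_free_diffusion <- function(d = 2L, R_p = 1, replicates = 200L,
                                   steps = 1e5, box_size = 50,
                                   config = sim_config(),
                                   sample_every = 50L, seed = 1L,
                                   window_frac = c(0.004, 0.05)) {
  sims <- lapply(seq_len(replicates), function(r) {
    sys <- empty_system(d, box_size) |>
      place_particles(n_binding = 0L, n_nonbinding = 1L, R_p = R_p,
                      seed = sub_seed(seed, r))
    simulate_gel(sys, rates = NULL, config = config, steps = steps,
                 seed = sub_seed(seed, 5000L + r),
                 sample_every = sample_every, record_events = FALSE)
  })
  msd <- compute_msd(sims)
  # short-lag window: time-averaged MSD estimates are noisiest at lags
  # comparable to the run length, and a free particle is diffusive at all
  # lags, so fitting early lags costs no bias and buys precision
  estimate_diffusion(msd, window = window_frac * max(msd$lag))
}

#' Run a caged-tracer experiment
#'
#' The full pipeline behind the MSD curves: build a periodic lattice gel,
#' saturate its crosslinks, insert one tracer (binding or non-binding),
#' equilibrate, then run the hybrid BD/Gillespie dynamics over independent
#' replicates and pool the mean squared displacement.
#'
#' @param model an [energy_model()].
#' @param binding logical: does the tracer bind to the crosslink sites?
#' @param stars_per_side,d gel geometry, see [build_gel()].
#' @param n_tracers tracers per run.  Non-binding tracers do not perturb the
#'   gel and almost never meet, so several can share one run as independent
#'   MSD series; binding tracers perturb their neighbourhood, so keep one
#'   per run unless particle-concentration effects are the point.
#' @param replicates independent runs (independent gels and noise).
#' @param steps production BD steps per replicate.
#' @param burnin equilibration BD steps discarded before measurement (the
#'   tracer origin is reset afterwards).
#' @param R_p tracer radius.
#' @param config a [sim_config()].
#' @param sample_every sampling stride.
#' @param seed base RNG seed; replicate seeds are derived from it.
#' @param record_events keep the bond-event log of each replicate.
#' @param msd_window optional lag window for the diffusion fit.
#' @return A `tracer_experiment`: `msd` (pooled), `fit` (a
#'   `diffusion_fit`), `trajectory`, `events`, `event_counts`, and the run
#'   metadata.
#' @export
run_tracer_experiment <- function(model, binding = TRUE,
                                  stars_per_side = 5L, d = 2L,
                                  n_tracers = 1L, replicates = 3L,
                                  steps = 1e6, burnin = 2e4, R_p = 1,
                                  config = sim_config(),
                                  sample_every = 200L, seed = 1L,
                                  record_events = FALSE,
                                  msd_window = NULL) {
  rates <- rates_from_energies(model, config$prefactor)
  sims <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    gel <- build_gel(stars_per_side, d = d) |>
      saturate_crosslinks() |>
      place_particles(n_binding = if (binding) n_tracers else 0L,
                      n_nonbinding = if (binding) 0L else n_tracers,
                      R_p = R_p, seed = sub_seed(seed, r))
    if (burnin > 0) {
      eq <- simulate_gel(gel, rates, config, steps = burnin,
                         seed = sub_seed(seed, 1000L + r),
                         sample_every = burnin, track = "none",
                         record_events = FALSE)
      gel <- eq$gel
    }
    sims[[r]] <- simulate_gel(gel, rates, config, steps = steps,
                              seed = sub_seed(seed, 2000L + r),
                              sample_every = sample_every,
                              record_events = record_events)
  }
  msd <- compute_msd(sims)
  fit <- estimate_diffusion(msd, window = msd_window)
  events <- bind_rows(lapply(seq_along(sims), function(r)
    mutate(sims[[r]]$events, rep = r)))
  structure(list(
    msd = msd, fit = fit,
    trajectory = as_trajectory(sims),
    events = events,
    event_counts = Reduce(`+`, lapply(sims, `[[`, "event_counts")),
    sims = sims,
    model = model, binding = binding, replicates = replicates,
    stars_per_side = stars_per_side, d = d, steps = steps, seed = seed
  ), class = "tracer_experiment")
}

#' @export
print.tracer_experiment <- function(x, ...) {
  cat(sprintf("<tracer_experiment> %s tracer, %dD gel (%d^%d stars), %d replicate(s)\n",
              if (x$binding) "binding" else "non-binding", x$d,
              x$stars_per_side, x$d, x$replicates))
  print(x$fit)
  invisible(x)
}

#' High-affinity parameter sweep of the tracer diffusivity
#'
#' Maps the binding-tracer diffusion constant over the two parameters that
#' matter in the high-affinity limit: the state-energy difference
#' `delta_E = E_b - E_c` and the exchange barrier
#' `delta_T = T_cb - max(E_c, E_b)`, with spontaneous crosslink breaking
#' suppressed (`T_fc = T_bf = 0` against states some 150 \eqn{k_B T} deep).
#' Each grid point reports \eqn{D/D_0} against the measured free-particle
#' diffusion constant.  Diffusion is fastest when the crosslinked, bound and
#' exchange transition-state energies are all roughly equal.
#'
#' @param delta_E,delta_T grid values (see above).
#' @param depth magnitude of the crosslinked-state energy.
#' @param D0 a precomputed free-particle `diffusion_fit` (measured if
#'   `NULL`).
#' @inheritParams run_tracer_experiment
#' @param ... passed on to [run_tracer_experiment()].
#' @return An `affinity_sweep` tibble: `delta_E`, `delta_T`, `D`, `D_se`,
#'   `r_squared`, `D0`, `D_ratio`.
#' @export
sweep_high_affinity <- function(delta_E = c(-0.5, 0, 0.5),
                                delta_T = c(0, 0.5, 1),
                                depth = 150.5, replicates = 3L,
                                D0 = NULL, config = sim_config(),
                                seed = 1L, ...) {
  if (is.null(D0))
    D0 <- measure_free_diffusion(config = config, seed = sub_seed(seed, 77L))
  grid <- expand.grid(delta_E = delta_E, delta_T = delta_T)
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    model <- high_affinity_model(grid$delta_E[g], grid$delta_T[g], depth)
    exp_ <- run_tracer_experiment(model, binding = TRUE,
                                  replicates = replicates, config = config,
                                  seed = sub_seed(seed, 100L + g), ...)
    rows[[g]] <- tibble(delta_E = grid$delta_E[g], delta_T = grid$delta_T[g],
                        D = exp_$fit$D, D_se = exp_$fit$se,
                        r_squared = exp_$fit$r_squared)
  }
  out <- bind_rows(rows)
  out$D0 <- D0$D
  out$D_ratio <- out$D / out$D0
  attr(out, "D0_fit") <- D0
  class(out) <- c("affinity_sweep", class(out))
  out
}

#' Shell filtering demonstration
#'
#' Builds a high-affinity gel trimmed to an annular shell, saturates it
#' (dangling boundary sites are deactivated), places binding and non-binding
#' particles in the interior cavity and runs the hybrid dynamics.  Binding
#' particles can enter the gel by crosslink exchange and eventually reach
#' the exterior; non-binding particles stay caged in the interior, so the
#' shell acts as a perfect filter.
#'
#' @param model energy landscape (default: canonical high-affinity).
#' @param stars_per_side lattice size before trimming.
#' @param n_binding,n_nonbinding particle counts placed in the cavity.
#' @param r_inner,r_outer shell trim radii (defaults `0.25 L`, `0.35 L` in
#'   the shell metric: a two-star-thick ring with a wide interior cavity,
#'   which keeps the density of particles per unit of fence length low --
#'   transient fence openings made by one particle are then rarely found
#'   by another).
#' @param metric shell geometry, see [trim_to_shell()].  The default square
#'   ring keeps every boundary a sealed crosslinked fence; a circular trim
#'   of a coarse lattice leaves staircase openings that leak sterically.
#' @param two_species build the shell with typed (`G`/`G'`) binding sites
#'   (see [build_gel()]): with many binding particles working the fences
#'   simultaneously, a self-complementary gel can rearrange its topology
#'   (two freed ends crosslink each other), leaving permanent holes; the
#'   typed gel always reseals.
#' @param steps,burnin production / equilibration BD steps.
#' @param R_p particle radius.
#' @param config a [sim_config()].
#' @param sample_every sampling stride.
#' @param seed RNG seed.
#' @return A `filter_demo`: region `counts` per frame and type, the `final`
#'   frame counts, the `sim`, and the shell geometry (`class_inner` /
#'   `class_outer` are the classification radii derived from the trimmed
#'   lattice: just inside the innermost fence line, and beyond the reach of
#'   the outermost dangling arms).
#' @export
run_filter_demo <- function(model = high_affinity_model(),
                            stars_per_side = 16L, n_binding = 10L,
                            n_nonbinding = 10L, r_inner = NULL,
                            r_outer = NULL,
                            metric = c("chebyshev", "euclidean"),
                            two_species = TRUE,
                            steps = 2e6, burnin = 1e4,
                            R_p = 1, config = sim_config(),
                            sample_every = 2000L, seed = 1L) {
  metric <- match.arg(metric)
  gel <- build_gel(stars_per_side, d = 2L, two_species = two_species)
  arm_reach <- 2 * gel$spacing + gel$R_m
  r_inner <- r_inner %||% (0.25 * gel$box[1])
  r_outer <- r_outer %||% (0.35 * gel$box[1])
  gel <- gel |>
    trim_to_shell(r_inner, r_outer, metric = metric) |>
    saturate_crosslinks(deactivate_remaining = TRUE)
  # star-center radii actually kept set the fence geometry
  cores <- gel$beads[gel$beads$role == "core", ]
  dxc <- abs(cbind(cores$x, cores$y) -
               matrix(gel$box / 2, nrow(cores), 2, byrow = TRUE))
  rc <- if (metric == "chebyshev") apply(dxc, 1, max)
        else sqrt(rowSums(dxc^2))
  class_inner <- min(rc) - 0.75   # just inside the innermost fence line
  # beyond the outermost crosslinked fence line (center clear of its beads);
  # the sparse dangling outward arms are spurs, not part of the gel boundary
  class_outer <- max(rc) + gel$R_m + R_p
  cavity_r <- min(rc) - arm_reach - R_p - 0.2
  ctr <- gel$box / 2
  region <- if (metric == "chebyshev") {
    function(pos) max(abs(pos - ctr)) <= cavity_r
  } else {
    region_disk(cavity_r, ctr)
  }
  # fence loops are identified from the rest geometry, before any dynamics
  loops <- if (metric == "chebyshev") fence_loops(gel) else NULL
  gel <- place_particles(gel, n_binding, n_nonbinding, region = region,
                         R_p = R_p, seed = sub_seed(seed, 11L))
  rates <- rates_from_energies(model, config$prefactor)
  if (burnin > 0) {
    eq <- simulate_gel(gel, rates, config, steps = burnin,
                       seed = sub_seed(seed, 22L), sample_every = burnin,
                       track = "none", record_events = FALSE)
    gel <- eq$gel
  }
  track <- if (is.null(loops)) "particles" else
    c(loops$inner, loops$outer,
      gel$beads$id[gel$beads$role == "particle"])
  sim <- simulate_gel(gel, rates, config, steps = steps,
                      seed = sub_seed(seed, 33L),
                      sample_every = sample_every, track = track,
                      record_events = FALSE)
  # classify against the instantaneous fence polygons (drift- and
  # deformation-proof); lab-frame radii are kept only for circular trims
  counts <- if (is.null(loops))
    count_regions(sim, class_inner, class_outer, metric = metric)
  else count_fence_regions(sim, loops)
  final <- counts[counts$time == max(counts$time), , drop = FALSE]
  structure(list(counts = counts, final = final, sim = sim, loops = loops,
                 r_inner = r_inner, r_outer = r_outer,
                 class_inner = class_inner, class_outer = class_outer,
                 metric = metric,
                 n_binding = n_binding, n_nonbinding = n_nonbinding,
                 seed = seed),
            class = "filter_demo")
}

#' @export
print.filter_demo <- function(x, ...) {
  cat(sprintf("<filter_demo> shell [%.3g, %.3g], %d binding + %d non-binding particles\n",
              x$r_inner, x$r_outer, x$n_binding, x$n_nonbinding))
  cat("final frame:\n")
  print(as.data.frame(tidyr::pivot_wider(x$final, names_from = "region",
                                         values_from = "n")))
  invisible(x)
}
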