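#' Time-origin-averaged mean squared displacement
#'
#' Computes the MSD of tracked beads from their unwrapped coordinates,
#' averaging over all time origins within each series and then across series
#' (beads and replicate runs).  The between-series spread provides the
#' standard error.
#'
#' @param x a `gel_sim`, a list of `gel_sim` replicates, or a trajectory
#'   tibble with columns `time`, `bead`, unwrapped coordinates `ux`, `uy`
#'   (and `uz` in 3D), and optionally `rep`.
#' @param lags lag times at which to evaluate the MSD (must be multiples of
#'   the sampling interval); by default about 40 log-spaced lags plus zero.
#' @param nlags number of default lags.
#' @param relative if `TRUE` (default) and the trajectory carries the gel
#'   center-of-mass drift columns (`gx`, `gy`, ...), displacements are
#'   measured relative to the gel network.  This removes the free diffusion
#'   of the whole periodic gel, which would otherwise contaminate the MSD of
#'   a caged tracer in a small simulation box.
#' @return An `msd_result` tibble with columns `lag`, `msd`, `se`,
#'   `n_series`; the sampling interval, dimension and per-series MSD matrix
#'   travel along as attributes.
#' @export
compute_msd <- function(x, lags = NULL, nlags = 40L, relative = TRUE) {
  traj <- as_trajectory(x)
  d <- trajectory_dim(traj)
  gcols <- paste0("g", pos_cols(d))
  if (relative && all(gcols %in% names(traj))) {
    for (k in seq_len(d))
      traj[[upos_cols(d)[k]]] <- traj[[upos_cols(d)[k]]] - traj[[gcols[k]]]
  }
  keys <- c(if ("rep" %in% names(traj)) "rep", if ("bead" %in% names(traj)) "bead")
  series <- split(traj, traj[keys], drop = TRUE)
  if (length(series) == 0L) abort("no trajectory series to analyse")
  tt <- sort(unique(series[[1L]]$time))
  if (length(tt) < 2L) abort("trajectory has fewer than two frames")
  dt_s <- tt[2L] - tt[1L]
  nT <- length(tt)
  if (is.null(lags)) {
    idx <- unique(round(exp(seq(0, log(nT - 1L), length.out = nlags))))
  } else {
    idx <- unique(round(lags / dt_s))
    idx <- idx[idx >= 1L]
    if (any(lags > (nT - 1L) * dt_s + 1e-9))
      abort("requested lag exceeds the trajectory span")
  }
  idx <- sort(idx[idx <= nT - 1L])
  per <- matrix(NA_real_, length(idx), length(series))
  for (s in seq_along(series)) {
    ss <- series[[s]][order(series[[s]]$time), , drop = FALSE]
    P <- as.matrix(ss[, upos_cols(d)])
    for (q in seq_along(idx)) {
      l <- idx[q]
      dd <- P[(1L + l):nT, , drop = FALSE] - P[1L:(nT - l), , drop = FALSE]
      per[q, s] <- mean(rowSums(dd * dd))
    }
  }
  msd <- rowMeans(per)
  se <- if (ncol(per) > 1L) apply(per, 1L, sd) / sqrt(ncol(per)) else
    rep(NA_real_, nrow(per))
  out <- tibble(lag = c(0, idx * dt_s), msd = c(0, msd), se = c(0, se),
                n_series = ncol(per))
  attr(out, "d") <- d
  attr(out, "dt_sample") <- dt_s
  attr(out, "series") <- per
  attr(out, "series_lags") <- idx * dt_s
  class(out) <- c("msd_result", class(out))
  out
}

as_trajectory <- function(x) {
  if (inherits(x, "gel_sim")) return(x$trajectory)
  if (is.data.frame(x)) return(x)
  if (is.list(x)) {
    parts <- lapply(seq_along(x), function(i) {
      tr <- if (inherits(x[[i]], "gel_sim")) x[[i]]$trajectory else x[[i]]
      tr$rep <- i
      tr
    })
    return(bind_rows(parts))
  }
  abort("cannot interpret `x` as a trajectory")
}

trajectory_dim <- function(traj) {
  sum(c("ux", "uy", "uz") %in% names(traj))
}

#' Diffusion constant from the long-time MSD slope
#'
#' Fits `MSD = 2 d D lag + c` by least squares over a lag window (by default
#' the last decade of available lags, where the MSD of a diffusing particle
#' is linear) and reports \eqn{D} with an uncertainty taken from the spread
#' of per-series slopes when replicates are available.  A low \eqn{R^2}
#' indicates the window sits in a sub-diffusive or plateau regime -- for a
#' permanently caged particle the fitted \eqn{D} is consistent with zero and
#' the linearity diagnostic flags the plateau.
#'
#' @param msd an `msd_result` from [compute_msd()].
#' @param window numeric `c(min, max)` lag-time window; default
#'   `c(max/10, max)`.
#' @param d spatial dimension (taken from the MSD attributes by default).
#' @return A `diffusion_fit` object with elements `D`, `se`, `r_squared`,
#'   `window`, `n_series`, `D_series`.  Has [generics::tidy()] and
#'   [generics::glance()] methods.
#' @export
estimate_diffusion <- function(msd, window = NULL, d = NULL) {
  d <- d %||% attr(msd, "d")
  if (is.null(d)) abort("spatial dimension unknown; pass `d`")
  lag_max <- max(msd$lag)
  window <- window %||% c(lag_max / 10, lag_max)
  use <- msd$lag >= window[1] & msd$lag <= window[2] & msd$lag > 0
  if (sum(use) < 2L) abort("fit window contains fewer than two lags")
  fit <- lm(msd ~ lag, data = msd[use, ])
  slope <- unname(coef(fit)[2L])
  D <- slope / (2 * d)
  r2 <- summary(fit)$r.squared
  per <- attr(msd, "series")
  D_series <- NULL
  se <- unname(sqrt(diag(stats::vcov(fit)))[2L]) / (2 * d)
  if (!is.null(per) && ncol(per) > 1L) {
    sl <- attr(msd, "series_lags")
    use_s <- sl >= window[1] & sl <= window[2]
    if (sum(use_s) >= 2L) {
      D_series <- apply(per[use_s, , drop = FALSE], 2L, function(y)
        unname(coef(lm(y ~ sl[use_s]))[2L]) / (2 * d))
      se <- sd(D_series) / sqrt(length(D_series))
    }
  }
  structure(list(D = D, se = se, r_squared = r2, slope = slope,
                 intercept = unname(coef(fit)[1L]), window = window,
                 d = d, n_series = attr(msd, "series") |>
                   (\(m) if (is.null(m)) 1L else ncol(m))(),
                 D_series = D_series),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> D = %.4g +/- %.2g (R^2 = %.3f, window [%g, %g], %d series)\n",
              x$D, x$se, x$r_squared, x$window[1], x$window[2], x$n_series))
  if (x$r_squared < 0.98)
    cat("  note: MSD not linear over the window (plateau / sub-diffusive?)\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# event-log replay: site state histories and crosslink intervals
# ---------------------------------------------------------------------------

# Replays the bond-event log from the initial site table, returning the
# crosslink intervals and (optionally) the full state history of one site.
replay_events <- function(sites_initial, events, t0, t_end,
                          history_site = NULL) {
  state <- setNames(sites_initial$state, sites_initial$bead)
  partner <- setNames(sites_initial$partner, sites_initial$bead)
  open <- list()   # key "i:j" -> list(t_form, near_form) for open intervals
  key <- function(i, j) paste0(min(i, j), ":", max(i, j))
  for (cl in sites_initial$bead[sites_initial$state == "crosslinked"]) {
    p <- partner[[as.character(cl)]]
    if (!is.na(p) && cl < p)
      open[[key(cl, p)]] <- list(t_form = NA_real_, near_form = NA_real_)
  }
  n_ev <- nrow(events)
  iv_a <- integer(0); iv_b <- integer(0)
  iv_form <- numeric(0); iv_break <- numeric(0)
  iv_type <- character(0); iv_nf <- numeric(0); iv_nb <- numeric(0)
  hist_t <- numeric(0); hist_s <- character(0)
  note <- function(sid, tm, st) {
    if (!is.null(history_site) && sid == history_site) {
      hist_t <<- c(hist_t, tm); hist_s <<- c(hist_s, st)
    }
  }
  close_iv <- function(i, j, tm, type, near) {
    k <- key(i, j)
    o <- open[[k]]
    if (!is.null(o)) {
      iv_a <<- c(iv_a, min(i, j)); iv_b <<- c(iv_b, max(i, j))
      iv_form <<- c(iv_form, o$t_form); iv_break <<- c(iv_break, tm)
      iv_type <<- c(iv_type, type)
      iv_nf <<- c(iv_nf, o$near_form); iv_nb <<- c(iv_nb, near)
      open[[k]] <<- NULL
    }
  }
  for (e in seq_len(n_ev)) {
    tm <- events$time[e]; ty <- events$type[e]
    i <- events$site[e]; j <- events$partner[e]
    ci <- as.character(i); cj <- as.character(j)
    if (ty == "fc") {
      state[ci] <- "crosslinked"; state[cj] <- "crosslinked"
      partner[ci] <- j; partner[cj] <- i
      open[[key(i, j)]] <- list(t_form = tm, near_form = events$near[e])
      note(i, tm, "crosslinked"); note(j, tm, "crosslinked")
    } else if (ty == "cf") {
      state[ci] <- "free"; state[cj] <- "free"
      partner[ci] <- NA_integer_; partner[cj] <- NA_integer_
      close_iv(i, j, tm, "cf", events$near[e])
      note(i, tm, "free"); note(j, tm, "free")
    } else if (ty == "cb") {
      gp <- partner[[ci]]
      close_iv(i, gp, tm, "cb", events$near[e])
      state[as.character(gp)] <- "free"
      partner[as.character(gp)] <- NA_integer_
      state[ci] <- "bound"; partner[ci] <- j
      note(i, tm, "bound"); note(gp, tm, "free")
    } else if (ty == "bc") {
      state[ci] <- "crosslinked"; state[cj] <- "crosslinked"
      partner[ci] <- j; partner[cj] <- i
      open[[key(i, j)]] <- list(t_form = tm, near_form = events$near[e])
      note(i, tm, "crosslinked"); note(j, tm, "crosslinked")
    } else if (ty == "fb") {
      state[ci] <- "bound"; partner[ci] <- j
      note(i, tm, "bound")
    } else if (ty == "bf") {
      state[ci] <- "free"; partner[ci] <- NA_integer_
      note(i, tm, "free")
    }
  }
  intervals <- tibble(
    site_a = iv_a, site_b = iv_b, t_form = iv_form, t_break = iv_break,
    lifetime = iv_break - iv_form, break_type = iv_type,
    near_at_form = iv_nf, near_at_break = iv_nb
  )
  history <- NULL
  if (!is.null(history_site)) {
    init <- sites_initial$state[sites_initial$bead == history_site]
    history <- tibble(time = c(t0, hist_t),
                      state = c(init, hist_s))
  }
  list(intervals = intervals, history = history, final_state = state)
}

#' Time-weighted state occupancy of a binding site
#'
#' Reconstructs one site's state history from the bond-event log of a
#' simulation and returns the fraction of time spent free, crosslinked and
#' bound.  For a frozen-geometry, kinetics-only run this converges to the
#' closed-form three-state equilibrium occupancies.
#'
#' @param sim a `gel_sim` with a recorded event log.
#' @param site bead id of the binding site.
#' @return Tibble with `state` and occupancy `fraction`.
#' @export
site_occupancy <- function(sim, site) {
  rp <- replay_events(sim$sites_initial, sim$events, sim$t0, sim$t_end,
                      history_site = site)
  h <- rp$history
  tt <- c(h$time, sim$t_end)
  dur <- diff(tt)
  agg <- tapply(dur, factor(h$state,
                            levels = c("free", "crosslinked", "bound")),
                sum, default = 0)
  tibble(state = names(agg),
         fraction = as.numeric(agg) / (sim$t_end - sim$t0))
}

#' Crosslink lifetime statistics from a bond-event log
#'
#' Extracts completed crosslink intervals (formation and breaking both
#' observed inside the run; intervals already open at the start are
#' censored and excluded) and reports the mean lifetime, overall and
#' stratified by whether a binding particle was within `near_cutoff` of the
#' site when the interval was formed or broken.  Without particles the mean
#' lifetime approaches \eqn{1/k_{cf}} (up to the overlap gating of the
#' breaking transition); a nearby binding particle opens the direct-exchange
#' channel and strictly shortens it.
#'
#' @param sim a `gel_sim` (simulated with `record_events = TRUE`).
#' @param near_cutoff center-to-center distance below which a binding
#'   particle counts as present (default: contact distance of a particle and
#'   a monomer plus one monomer diameter).
#' @return List with `intervals` (tibble of completed intervals) and
#'   `summary` (mean lifetime overall / particle-near / particle-far).
#' @export
measure_crosslink_lifetime <- function(sim, near_cutoff = 2.5) {
  stopifnot(inherits(sim, "gel_sim"))
  if (nrow(sim$events) == 0L)
    abort("no events recorded: cannot measure lifetimes")
  rp <- replay_events(sim$sites_initial, sim$events, sim$t0, sim$t_end)
  iv <- rp$intervals
  iv <- iv[!is.na(iv$t_form), , drop = FALSE]
  if (nrow(iv) == 0L)
    abort("no completed crosslink lifetimes in the event log")
  iv$particle_near <- pmin(iv$near_at_form, iv$near_at_break,
                           na.rm = TRUE) < near_cutoff
  mk <- function(x) tibble(mean = mean(x), se = sd(x) / sqrt(length(x)),
                           n = length(x))
  summary <- bind_rows(
    mutate(mk(iv$lifetime), group = "all"),
    if (any(iv$particle_near))
      mutate(mk(iv$lifetime[iv$particle_near]), group = "particle_near"),
    if (any(!iv$particle_near))
      mutate(mk(iv$lifetime[!iv$particle_near]), group = "particle_far")
  )
  list(intervals = iv, summary = select(summary, group, mean, se, n))
}

#' Self-healing time from partner-exchange statistics
#'
#' The self-healing time is the scale on which the gel's crosslink
#' *structure* turns over.  A crosslink that breaks and re-forms between the
#' same two ends has not changed the structure, so individual crosslink
#' lifetimes underestimate healing badly; instead, consecutive completed
#' intervals of the same site pair are merged into partnership episodes
#' (including the free gaps between them), and the healing time is the mean
#' episode duration -- the time until a site trades partners.
#'
#' @param sim a `gel_sim` with a recorded event log.
#' @return List with the merged `episodes` tibble and the mean `tau_h` (with
#'   `se` and `n`).
#' @export
measure_healing_time <- function(sim) {
  stopifnot(inherits(sim, "gel_sim"))
  rp <- replay_events(sim$sites_initial, sim$events, sim$t0, sim$t_end)
  iv <- rp$intervals
  iv <- iv[!is.na(iv$t_form), , drop = FALSE]
  if (nrow(iv) == 0L) abort("no completed crosslink intervals in the log")
  # per-site chronology: runs of consecutive intervals with the same partner
  long <- bind_rows(
    tibble(site = iv$site_a, partner = iv$site_b,
           t_form = iv$t_form, t_break = iv$t_break),
    tibble(site = iv$site_b, partner = iv$site_a,
           t_form = iv$t_form, t_break = iv$t_break))
  episodes <- long |>
    group_by(.data$site) |>
    arrange(.data$t_form, .by_group = TRUE) |>
    mutate(run = cumsum(c(1L, diff(.data$partner) != 0L))) |>
    group_by(.data$site, .data$run) |>
    summarise(partner = .data$partner[1L],
              t_start = min(.data$t_form), t_end = max(.data$t_break),
              n_intervals = dplyr::n(), .groups = "drop_last") |>
    ungroup() |>
    mutate(duration = .data$t_end - .data$t_start)
  # runs that reach the end of the log are censored lower bounds on the
  # partner-exchange time; they are kept, so tau_h is a conservative
  # (downward-biased) estimate of the true healing time
  tau_h <- mean(episodes$duration)
  list(episodes = episodes,
       tau_h = tau_h,
       se = sd(episodes$duration) / sqrt(nrow(episodes)),
       n = nrow(episodes))
}

#' Radial region occupancy over time
#'
#' Classifies every tracked particle frame as interior, shell or exterior by
#' its wrapped radial distance from the box center, and counts particles per
#' region, frame and particle type.  Used by the shell filtering
#' demonstration.
#'
#' @param sim a `gel_sim` whose trajectory tracks particles.
#' @param r_inner,r_outer shell radii.
#' @param metric distance metric matching the shell geometry (see
#'   [trim_to_shell()]).
#' @return Tibble with `time`, `binding`, `region`, `n` (all combinations,
#'   zero-filled).
#' @export
count_regions <- function(sim, r_inner, r_outer,
                          metric = c("euclidean", "chebyshev")) {
  metric <- match.arg(metric)
  traj <- sim$trajectory
  d <- sim$d
  ctr <- sim$box / 2
  dx <- sweep(as.matrix(traj[, pos_cols(d)]), 2, ctr)
  r <- if (metric == "euclidean") sqrt(rowSums(dx^2)) else
    apply(abs(dx), 1, max)
  traj$region <- cut(r, c(-Inf, r_inner, r_outer, Inf),
                     labels = c("interior", "shell", "exterior"))
  counts <- traj |>
    group_by(.data$time, .data$binding, .data$region) |>
    summarise(n = dplyr::n(), .groups = "drop")
  tidyr::complete(counts, .data$time, .data$binding, .data$region,
                  fill = list(n = 0L))
}
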