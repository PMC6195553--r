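#' Run configuration
#'
#' A `run_config` captures everything needed to reproduce a run: the energy
#' landscape, the mechanical/numerical parameters, the gel geometry, the
#' particle complement, optional shell trimming, and the seed.  It
#' round-trips losslessly through YAML ([write_run_config()] /
#' [read_run_config()]); unknown keys are rejected rather than ignored, and
#' every default is resolved and recorded explicitly.
#'
#' @param energies named list with `E_c`, `E_b`, `T_fc`, `T_cb`, `T_bf`
#'   (units \eqn{k_B T}); validated through [energy_model()].
#' @param sim,gel,particles,shell,output optional named lists overriding the
#'   section defaults (see the package vignette for the schema).
#' @param seed integer seed.
#' @return A validated `run_config` object.
#' @export
run_config <- function(energies, sim = list(), gel = list(),
                       particles = list(), shell = list(), output = list(),
                       seed = 1L) {
  as_run_config(list(schema = "geldiff-config/1", seed = seed,
                     energies = energies, sim = sim, gel = gel,
                     particles = particles, shell = shell, output = output))
}

config_defaults <- function() {
  list(
    sim = list(dt = 0.005, k_H = 400, k_BB = 200, eta = 1, kT = 1,
               steps = 1e5, prefactor = 1, sample_every = 100L,
               capacity = 1L),
    gel = list(stars_per_side = 8L, d = 2L, R_m = 0.5, spacing = 1,
               overlap = 0.1),
    particles = list(n_binding = 1L, n_nonbinding = 0L, R_p = 1),
    shell = list(enabled = FALSE, r_inner = NA_real_, r_outer = NA_real_),
    output = list(dir = ".")
  )
}

merge_section <- function(given, defaults, section) {
  given <- given %||% list()
  unknown <- setdiff(names(given), names(defaults))
  if (length(unknown))
    abort(sprintf("unknown key(s) in config section '%s': %s", section,
                  paste(unknown, collapse = ", ")))
  defaults[names(given)] <- given
  defaults
}

as_run_config <- function(x) {
  top_known <- c("schema", "seed", "energies", "sim", "gel", "particles",
                 "shell", "output")
  unknown <- setdiff(names(x), top_known)
  if (length(unknown))
    abort(sprintf("unknown top-level config key(s): %s",
                  paste(unknown, collapse = ", ")))
  if (is.null(x$energies)) abort("config is missing the 'energies' section")
  e_known <- c("E_c", "E_b", "T_fc", "T_cb", "T_bf")
  missing <- setdiff(e_known, names(x$energies))
  if (length(missing))
    abort(sprintf("config 'energies' is missing: %s",
                  paste(missing, collapse = ", ")))
  unknown <- setdiff(names(x$energies), e_known)
  if (length(unknown))
    abort(sprintf("unknown key(s) in config section 'energies': %s",
                  paste(unknown, collapse = ", ")))
  # validates the transition-state inequalities, naming the violated one
  do.call(energy_model, x$energies)
  def <- config_defaults()
  out <- list(
    schema = x$schema %||% "geldiff-config/1",
    seed = as.integer(x$seed %||% 1L),
    energies = x$energies[e_known],
    sim = merge_section(x$sim, def$sim, "sim"),
    gel = merge_section(x$gel, def$gel, "gel"),
    particles = merge_section(x$particles, def$particles, "particles"),
    shell = merge_section(x$shell, def$shell, "shell"),
    output = merge_section(x$output, def$output, "output")
  )
  if (!identical(out$schema, "geldiff-config/1"))
    abort(sprintf("unsupported config schema '%s'", out$schema))
  structure(out, class = "run_config")
}

#' @rdname run_config
#' @param path file path of a YAML run configuration.
#' @export
read_run_config <- function(path) {
  as_run_config(yaml::read_yaml(path))
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>", x$schema, "seed", x$seed, "\n")
  cat(yaml::as.yaml(unclass(x), precision = 15L))
  invisible(x)
}

# build the gel/particle system a run_config describes
build_from_config <- function(config) {
  g <- config$gel
  p <- config$particles
  gel <- build_gel(g$stars_per_side, d = g$d, spacing = g$spacing,
                   R_m = g$R_m, overlap = g$overlap)
  if (isTRUE(config$shell$enabled)) {
    ri <- config$shell$r_inner
    ro <- config$shell$r_outer
    if (is.na(ri)) ri <- 0.25 * gel$box[1]
    if (is.na(ro)) ro <- 0.45 * gel$box[1]
    gel <- trim_to_shell(gel, ri, ro) |>
      saturate_crosslinks(deactivate_remaining = TRUE) |>
      place_particles(p$n_binding, p$n_nonbinding,
                      region = region_disk(ri - p$R_p - 0.2, gel$box / 2),
                      R_p = p$R_p, seed = config$seed)
  } else {
    gel <- saturate_crosslinks(gel) |>
      place_particles(p$n_binding, p$n_nonbinding, R_p = p$R_p,
                      seed = config$seed)
  }
  gel
}

config_sim <- function(config) {
  s <- config$sim
  sim_config(dt = s$dt, k_H = s$k_H, k_BB = s$k_BB, eta = s$eta, kT = s$kT,
             steps = s$steps, seed = config$seed, prefactor = s$prefactor,
             sample_every = s$sample_every, capacity = s$capacity)
}

# ---------------------------------------------------------------------------
# extended-XYZ frames
# ---------------------------------------------------------------------------

species_letter <- c(core = "C", arm = "A", end = "E", particle = "P")

#' Write and read gel snapshots as extended XYZ
#'
#' Each frame is an extended-XYZ block whose comment line carries the
#' periodic lattice, the property schema and the frame time; per-bead
#' columns record species, position (17 significant digits, so positions
#' round-trip bit-for-bit), radius, role, site state and the binding flag.
#' The dynamic bond table of every frame goes to a sidecar TSV
#' (`<path>.bonds.tsv`) with columns `frame`, `i`, `j`, `kind`.
#'
#' @param x a `gel_system` or a list of them (one per frame).
#' @param path output file.
#' @param times frame times written to the headers.
#' @return `path`, invisibly.
#' @export
write_frames <- function(x, path, times = NULL) {
  frames <- if (inherits(x, "gel_system")) list(x) else x
  times <- times %||% (seq_along(frames) - 1)
  con <- file(path, "w")
  on.exit(close(con))
  bonds_rows <- list()
  for (f in seq_along(frames)) {
    gel <- frames[[f]]
    d <- gel$d
    b <- gel$beads
    L3 <- c(gel$box, rep(0, 3 - d))
    lattice <- sprintf("%.17g %.17g %.17g %.17g %.17g %.17g %.17g %.17g %.17g",
                       L3[1], 0, 0, 0, L3[2], 0, 0, 0, L3[3])
    writeLines(as.character(nrow(b)), con)
    writeLines(sprintf(
      'Lattice="%s" Properties=species:S:1:pos:R:3:radius:R:1:role:S:1:site_state:S:1:binding:I:1:id:I:1 Time=%.17g',
      lattice, times[f]), con)
    pos <- as.matrix(b[, pos_cols(d), drop = FALSE])
    if (d == 2) pos <- cbind(pos, 0)
    state <- rep("none", nrow(b))
    m <- match(b$id, gel$sites$bead)
    has <- !is.na(m)
    state[has] <- ifelse(gel$sites$active[m[has]], gel$sites$state[m[has]],
                         "inactive")
    if (nrow(b))
      writeLines(sprintf("%s %.17g %.17g %.17g %.17g %s %s %d %d",
                         species_letter[b$role], pos[, 1], pos[, 2], pos[, 3],
                         b$radius, b$role, state, as.integer(b$binding),
                         b$id), con)
    cl <- gel$sites[gel$sites$state == "crosslinked" &
                      !is.na(gel$sites$partner) &
                      gel$sites$bead < gel$sites$partner, , drop = FALSE]
    gp <- gel$sites[gel$sites$state == "bound", , drop = FALSE]
    bonds_rows[[f]] <- bind_rows(
      tibble(frame = f, i = gel$bonds$i, j = gel$bonds$j, kind = "permanent"),
      tibble(frame = f, i = cl$bead, j = cl$partner, kind = "crosslink"),
      tibble(frame = f, i = gp$bead, j = gp$partner, kind = "particle")
    )
  }
  readr::write_tsv(bind_rows(bonds_rows) %||%
                     tibble(frame = integer(0), i = integer(0),
                            j = integer(0), kind = character(0)),
                   paste0(path, ".bonds.tsv"), progress = FALSE)
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path) {
  lines <- readLines(path)
  bonds_path <- paste0(path, ".bonds.tsv")
  bonds <- if (file.exists(bonds_path))
    readr::read_tsv(bonds_path, show_col_types = FALSE, progress = FALSE)
  else NULL
  frames <- list()
  i <- 1L
  f <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- as.integer(lines[i])
    header <- lines[i + 1L]
    f <- f + 1L
    lat <- regmatches(header, regexec('Lattice="([^"]*)"', header))[[1]][2]
    lat <- as.numeric(strsplit(lat, " ")[[1]])
    tm <- regmatches(header, regexec("Time=([-0-9.eE+]+)", header))[[1]][2]
    rows <- lines[(i + 2L):(i + 1L + n)]
    if (n > 0) {
      parts <- do.call(rbind, strsplit(rows, " +"))
      beads <- tibble(
        species = parts[, 1], x = as.numeric(parts[, 2]),
        y = as.numeric(parts[, 3]), z = as.numeric(parts[, 4]),
        radius = as.numeric(parts[, 5]), role = parts[, 6],
        site_state = parts[, 7], binding = as.integer(parts[, 8]) == 1L,
        id = as.integer(parts[, 9]))
    } else {
      beads <- tibble(species = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), radius = numeric(0), role = character(0),
                      site_state = character(0), binding = logical(0),
                      id = integer(0))
    }
    d <- if (lat[9] == 0) 2L else 3L
    frames[[f]] <- list(
      beads = beads, time = as.numeric(tm),
      box = c(lat[1], lat[5], lat[9])[seq_len(d)], d = d,
      bonds = if (!is.null(bonds)) bonds[bonds$frame == f, c("i", "j", "kind")]
              else NULL)
    i <- i + 2L + n
  }
  frames
}

#' Write and read a trajectory table
#'
#' Unwrapped (and wrapped) tracer coordinates as a plain TSV with
#' full-precision numbers.
#'
#' @param x a `gel_sim` or trajectory tibble.
#' @param path file path.
#' @return `path` (write) or the trajectory tibble (read).
#' @export
write_trajectory <- function(x, path) {
  traj <- as_trajectory(x)
  out <- traj
  for (cc in names(out))
    if (is.double(out[[cc]])) out[[cc]] <- sprintf("%.17g", out[[cc]])
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
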