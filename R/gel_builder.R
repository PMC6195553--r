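#' Build a single star-shaped polymer
#'
#' A star polymer is a central monomer with arms of two monomers each,
#' radiating along the coordinate axes: 4 arms (9 beads) in two dimensions,
#' 6 arms (13 beads) in three.  Consecutive beads are joined by permanent
#' bonds; the outermost bead of each arm carries a crosslink binding site.
#'
#' @param center numeric position of the core bead (length `d`).
#' @param d dimension, 2 or 3.
#' @param spacing distance between consecutive beads along an arm.  The
#'   default, `2 * R_m`, places bonded beads exactly at contact, the rest
#'   length of the two-sided harmonic bond.
#' @param R_m monomer radius.
#' @param star_id integer id stamped on the beads.
#' @param bead_offset id of the last existing bead (for concatenation).
#' @return A list with `beads`, `bonds`, `triples` tibbles and `end_ids`.
#' @examples
#' star <- build_star(c(0, 0))
#' nrow(star$beads)  # 9 monomers
#' @export
build_star <- function(center = c(0, 0), d = length(center),
                       spacing = 2 * R_m, R_m = 0.5,
                       star_id = 1L, bead_offset = 0L) {
  if (!d %in% c(2L, 3L)) abort("`d` must be 2 or 3")
  if (spacing <= 0) abort("`spacing` must be > 0")
  center <- as.numeric(center)
  if (length(center) != d) abort("`center` must have length `d`")
  dirs <- rbind(diag(d), -diag(d))
  n_arms <- nrow(dirs)
  n_beads <- 1L + 2L * n_arms
  pos <- matrix(0, n_beads, d)
  role <- character(n_beads)
  pos[1L, ] <- center
  role[1L] <- "core"
  bonds <- matrix(0L, 0L, 2L)
  triples <- matrix(0L, 0L, 3L)
  row <- 1L
  for (a in seq_len(n_arms)) {
    mid <- row + 1L
    end <- row + 2L
    pos[mid, ] <- center + dirs[a, ] * spacing
    pos[end, ] <- center + dirs[a, ] * 2 * spacing
    role[c(mid, end)] <- c("arm", "end")
    bonds <- rbind(bonds, c(1L, mid), c(mid, end))
    # bond-bending acts on consecutive triples along one strand (core ->
    # arm -> end); triples spanning two arms across the core are excluded
    triples <- rbind(triples, c(1L, mid, end))
    row <- end
  }
  ids <- bead_offset + seq_len(n_beads)
  arm_of <- rep(NA_integer_, n_beads)
  for (a in seq_len(n_arms)) arm_of[1L + 2L * (a - 1L) + 1:2] <- a
  beads <- tibble(
    id = ids, star = star_id, role = role, arm = arm_of,
    binding = FALSE, radius = R_m, mobile = TRUE
  )
  for (k in seq_len(d)) beads[[upos_cols(d)[k]]] <- pos[, k]
  list(
    beads = beads,
    bonds = tibble(i = ids[bonds[, 1L]], j = ids[bonds[, 2L]]),
    triples = tibble(h = ids[triples[, 1L]], i = ids[triples[, 2L]],
                     j = ids[triples[, 3L]]),
    end_ids = ids[role == "end"]
  )
}

#' Build a periodic lattice gel of star polymers
#'
#' Stars are placed on a square (cubic) lattice with the lattice constant
#' chosen so that the strand ends of neighbouring stars overlap slightly at
#' rest (`overlap` is the rest-state overlap depth of facing ends).  The box
#' is periodic, so facing ends across the boundary overlap too; saturating
#' the crosslinks then yields a spanning gel with no free binding sites.
#'
#' @param stars_per_side number of stars along each box edge (>= 2).
#' @param d dimension, 2 or 3.
#' @param spacing,R_m per-arm geometry, see [build_star()].
#' @param overlap rest-state overlap depth of facing strand ends; must be
#'   positive or the gel cannot crosslink.
#' @param two_species if `TRUE`, ends on positive-axis arms carry `G` sites
#'   and ends on negative-axis arms carry `G'` sites, so facing ends of
#'   neighbouring stars are always complementary and only `G`-`G'`
#'   crosslinks (and particle bonds to `G` sites) can form.  The default is
#'   the self-complementary gel; the mechanism is identical, but the typed
#'   gel forbids the multi-particle topology rearrangement in which two
#'   simultaneously freed ends crosslink each other and leave their original
#'   partners permanently particle-bound.
#' @param seed unused (construction is deterministic); accepted so callers
#'   can treat all builders uniformly.
#' @return A `gel_system`: a classed list with tibbles `beads`, `bonds`
#'   (permanent), `sites`, `triples`, plus the periodic `box`, dimension `d`
#'   and lattice constant `a`.
#' @examples
#' gel <- build_gel(2)
#' gel
#' @export
build_gel <- function(stars_per_side = 8L, d = 2L, spacing = 2 * R_m,
                      R_m = 0.5, overlap = 0.2 * R_m, two_species = FALSE,
                      seed = NULL) {
  if (stars_per_side < 2L) abort("`stars_per_side` must be >= 2")
  if (!d %in% c(2L, 3L)) abort("`d` must be 2 or 3")
  a <- 4 * spacing + 2 * R_m - overlap
  if (overlap <= 0)
    abort("`overlap` must be > 0: facing strand ends would not overlap, so the gel could never crosslink")
  L <- rep(stars_per_side * a, d)
  grid <- do.call(expand.grid, rep(list(seq_len(stars_per_side) - 1L), d))
  beads <- vector("list", nrow(grid))
  bonds <- vector("list", nrow(grid))
  triples <- vector("list", nrow(grid))
  offset <- 0L
  for (s in seq_len(nrow(grid))) {
    center <- (as.numeric(grid[s, ]) + 0.5) * a
    star <- build_star(center, d = d, spacing = spacing, R_m = R_m,
                       star_id = as.integer(s), bead_offset = offset)
    beads[[s]] <- star$beads
    bonds[[s]] <- star$bonds
    triples[[s]] <- star$triples
    offset <- offset + nrow(star$beads)
  }
  beads <- bind_rows(beads)
  end_rows <- beads$role == "end"
  species <- if (two_species)
    ifelse(beads$arm[end_rows] <= d, "G", "Gp") else NA_character_
  gel <- structure(
    list(
      beads = beads,
      bonds = bind_rows(bonds),
      sites = tibble(bead = beads$id[end_rows],
                     state = "free", partner = NA_integer_, active = TRUE,
                     species = species),
      triples = bind_rows(triples),
      box = L, d = as.integer(d), a = a, spacing = spacing, R_m = R_m,
      meta = list(stars_per_side = as.integer(stars_per_side),
                  overlap = overlap, free_sites = NA_integer_)
    ),
    class = "gel_system"
  )
  refresh_wrapped(gel)
}

# keep wrapped coordinates in sync with the unwrapped ones
refresh_wrapped <- function(gel) {
  d <- gel$d
  for (k in seq_len(d)) {
    gel$beads[[pos_cols(d)[k]]] <-
      wrap_coord(gel$beads[[upos_cols(d)[k]]], gel$box[k])
  }
  gel
}

#' @export
print.gel_system <- function(x, ...) {
  ns <- length(unique(stats::na.omit(x$beads$star)))
  np <- sum(x$beads$role == "particle")
  st <- table(factor(x$sites$state, levels = c("free", "crosslinked", "bound")))
  cat(sprintf("<gel_system> %dD, box %s, %d stars, %d beads (%d particles)\n",
              x$d, paste(signif(x$box, 4), collapse = " x "), ns,
              nrow(x$beads), np))
  cat(sprintf("  sites: %d free, %d crosslinked, %d bound (%d inactive)\n",
              st[["free"]], st[["crosslinked"]], st[["bound"]],
              sum(!x$sites$active)))
  invisible(x)
}

# all pairwise gaps s_ij = r_ij - (R_i + R_j) between two id sets (min image)
pair_gaps <- function(gel, ids_a, ids_b = ids_a) {
  d <- gel$d
  bi <- match(ids_a, gel$beads$id)
  bj <- match(ids_b, gel$beads$id)
  A <- as.matrix(gel$beads[bi, upos_cols(d)])
  B <- as.matrix(gel$beads[bj, upos_cols(d)])
  out <- expand.grid(ai = seq_along(ids_a), bi = seq_along(ids_b))
  dx <- A[out$ai, , drop = FALSE] - B[out$bi, , drop = FALSE]
  dx <- min_image(dx, gel$box)
  r <- sqrt(rowSums(dx^2))
  tibble(i = ids_a[out$ai], j = ids_b[out$bi],
         gap = r - gel$beads$radius[bi][out$ai] - gel$beads$radius[bj][out$bi])
}

#' Saturate the crosslinks of a gel
#'
#' Greedily pairs overlapping free binding sites (closest pairs first) into
#' crosslinks until no overlapping free-free pair remains.  Binding sites are
#' self-complementary, so any two free strand ends may pair.  The
#' binding-enhanced filtering mechanism requires a saturated gel -- any free
#' site left in a high-affinity gel is a trap for binding particles -- so the
#' number of unsaturated sites is reported in `gel$meta$free_sites` and a
#' warning is raised if any remain (unless they are deactivated).
#'
#' @param gel a `gel_system`.
#' @param deactivate_remaining if `TRUE`, sites that cannot be paired (e.g.
#'   dangling strand ends on a trimmed shell boundary) are marked inactive:
#'   they keep their excluded-volume interaction but generate no binding
#'   events.
#' @return The gel, crosslinked; idempotent on already saturated gels.
#' @export
saturate_crosslinks <- function(gel, deactivate_remaining = FALSE) {
  stopifnot(inherits(gel, "gel_system"))
  free_ids <- gel$sites$bead[gel$sites$state == "free" & gel$sites$active]
  if (length(free_ids) > 1L) {
    cand <- pair_gaps(gel, free_ids)
    cand <- cand[cand$i < cand$j & cand$gap < 0, , drop = FALSE]
    if ("species" %in% names(gel$sites)) {
      sp <- gel$sites$species[match(cand$i, gel$sites$bead)]
      sp_j <- gel$sites$species[match(cand$j, gel$sites$bead)]
      ok <- (is.na(sp) & is.na(sp_j)) |
        (!is.na(sp) & !is.na(sp_j) & sp != sp_j)
      cand <- cand[ok, , drop = FALSE]
    }
    cand <- cand[order(cand$gap), , drop = FALSE]
    paired <- integer(0)
    for (row in seq_len(nrow(cand))) {
      i <- cand$i[row]; j <- cand$j[row]
      if (i %in% paired || j %in% paired) next
      gel$sites$state[gel$sites$bead %in% c(i, j)] <- "crosslinked"
      gel$sites$partner[gel$sites$bead == i] <- j
      gel$sites$partner[gel$sites$bead == j] <- i
      paired <- c(paired, i, j)
    }
  }
  remaining <- sum(gel$sites$state == "free" & gel$sites$active)
  if (remaining > 0 && deactivate_remaining) {
    gel$sites$active[gel$sites$state == "free"] <- FALSE
    gel$meta$free_sites <- 0L
  } else {
    gel$meta$free_sites <- remaining
    if (remaining > 0)
      warn(sprintf(
        "gel not fully saturated: %d free binding site(s) remain", remaining))
  }
  gel
}

#' Trim a gel to an annular shell
#'
#' Deletes every star whose center lies outside the radial band
#' `[r_inner, r_outer]` around the box center.  Stars are removed whole --
#' permanent bonds are never severed, since that would amount to polymer
#' degradation rather than reversible crosslink dynamics.  Crosslinks whose
#' partner star was removed are reset to free.
#'
#' @param gel a `gel_system`.
#' @param r_inner,r_outer shell radii; defaults are `0.25 * L` and
#'   `0.45 * L`.  `r_inner = 0` keeps a full disk; `r_outer` at or beyond
#'   the box circumradius only carves the interior cavity.
#' @param metric `"euclidean"` for a circular shell, `"chebyshev"` for a
#'   square ring.  On a coarse star lattice a circular boundary is a 45
#'   degree staircase whose corner openings can line up into continuous
#'   steric channels; a square ring keeps every boundary a sealed
#'   crosslinked fence line, which the filtering demonstration relies on.
#' @return The trimmed `gel_system`.
#' @export
trim_to_shell <- function(gel, r_inner = NULL, r_outer = NULL,
                          metric = c("euclidean", "chebyshev")) {
  metric <- match.arg(metric)
  stopifnot(inherits(gel, "gel_system"))
  L <- gel$box
  r_inner <- r_inner %||% (0.25 * L[1])
  r_outer <- r_outer %||% (0.45 * L[1])
  if (r_inner < 0 || r_outer <= r_inner)
    abort("need 0 <= r_inner < r_outer")
  d <- gel$d
  ctr <- L / 2
  gel_beads <- gel$beads[gel$beads$role != "particle", , drop = FALSE]
  centers <- gel_beads[gel_beads$role == "core", , drop = FALSE]
  cc <- as.matrix(centers[, pos_cols(d)])
  rr <- if (metric == "euclidean") sqrt(rowSums(sweep(cc, 2, ctr)^2))
        else apply(abs(sweep(cc, 2, ctr)), 1, max)
  # tolerance so stars sitting exactly on a boundary radius are kept on
  # every side (lattice radii are sums of floating-point terms)
  tol <- 1e-7 * max(L)
  keep_stars <- centers$star[rr >= r_inner - tol & rr <= r_outer + tol]
  if (length(keep_stars) == 0L)
    abort("shell too thin: no star center falls inside [r_inner, r_outer]")
  keep <- (gel$beads$star %in% keep_stars) | gel$beads$role == "particle"
  keep_ids <- gel$beads$id[keep]
  id_map <- setNames(seq_along(keep_ids), keep_ids)
  remap <- function(v) unname(id_map[as.character(v)])
  beads <- gel$beads[keep, , drop = FALSE]
  beads$id <- seq_len(nrow(beads))
  bonds <- gel$bonds[gel$bonds$i %in% keep_ids & gel$bonds$j %in% keep_ids, ]
  bonds$i <- remap(bonds$i); bonds$j <- remap(bonds$j)
  tri <- gel$triples[gel$triples$h %in% keep_ids &
                       gel$triples$i %in% keep_ids &
                       gel$triples$j %in% keep_ids, ]
  tri$h <- remap(tri$h); tri$i <- remap(tri$i); tri$j <- remap(tri$j)
  sites <- gel$sites[gel$sites$bead %in% keep_ids, , drop = FALSE]
  # partners that were trimmed away leave the surviving site free
  lost <- !is.na(sites$partner) & !(sites$partner %in% keep_ids)
  sites$state[lost] <- "free"
  sites$partner[lost] <- NA_integer_
  sites$bead <- remap(sites$bead)
  sites$partner[!is.na(sites$partner)] <-
    remap(sites$partner[!is.na(sites$partner)])
  gel$beads <- beads; gel$bonds <- bonds; gel$triples <- tri
  gel$sites <- sites
  gel$meta$r_inner <- r_inner
  gel$meta$r_outer <- r_outer
  gel$meta$shell_metric <- metric
  audit_gel(gel)
}

#' Insert tracer particles into a gel
#'
#' Particles are placed uniformly at random inside `region`, rejecting
#' positions that overlap any gel bead or a previously placed particle.
#' Binding particles interact with the crosslink binding sites through the
#' stochastic bond kinetics; non-binding particles are sterically identical
#' but generate no binding events.
#'
#' @param gel a `gel_system`.
#' @param n_binding,n_nonbinding numbers of particles of each type.
#' @param region `NULL` for the whole box, or a predicate
#'   `function(pos)` returning `TRUE` where insertion is allowed (`pos` is a
#'   length-`d` position).  See [region_disk()].
#' @param R_p particle radius.
#' @param seed optional RNG seed (the caller's RNG state is restored).
#' @param max_attempts rejection-sampling budget per particle.
#' @return The gel with particle beads appended.
#' @export
place_particles <- function(gel, n_binding = 1L, n_nonbinding = 0L,
                            region = NULL, R_p = 1, seed = NULL,
                            max_attempts = 20000L) {
  stopifnot(inherits(gel, "gel_system"))
  d <- gel$d
  n_new <- n_binding + n_nonbinding
  if (n_new == 0L) return(gel)
  with_seed(seed, {
    existing <- as.matrix(gel$beads[, upos_cols(d)])
    existing_R <- gel$beads$radius
    placed <- matrix(NA_real_, n_new, d)
    for (p in seq_len(n_new)) {
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        pos <- runif(d) * gel$box
        if (!is.null(region) && !isTRUE(region(pos))) next
        dx <- min_image(sweep(existing, 2, pos, "-"), gel$box)
        if (any(sqrt(rowSums(dx^2)) < existing_R + R_p)) next
        placed[p, ] <- pos
        existing <- rbind(existing, pos)
        existing_R <- c(existing_R, R_p)
        ok <- TRUE
        break
      }
      if (!ok)
        abort(sprintf(
          "could not insert particle %d after %d attempts: region has no free volume",
          p, max_attempts))
    }
    base_id <- if (nrow(gel$beads)) max(gel$beads$id) else 0L
    new <- tibble(
      id = base_id + seq_len(n_new),
      star = NA_integer_, role = "particle", arm = NA_integer_,
      binding = rep(c(TRUE, FALSE), c(n_binding, n_nonbinding)),
      radius = R_p, mobile = TRUE
    )
    for (k in seq_len(d)) new[[upos_cols(d)[k]]] <- placed[, k]
    gel$beads <- bind_rows(gel$beads, new)
    refresh_wrapped(gel)
  })
}

#' Disk-shaped insertion region
#'
#' @param r disk radius.
#' @param center disk center; defaults to the box center when used through
#'   [place_particles()] by passing the gel's `box/2` explicitly.
#' @return A predicate function for [place_particles()].
#' @export
region_disk <- function(r, center) {
  force(r); force(center)
  function(pos) sqrt(sum((pos - center)^2)) <= r
}

#' Audit the internal consistency of a gel
#'
#' Verifies the structural invariants that every builder and the stochastic
#' engine must preserve: mutual and exclusive crosslink partnerships, no site
#' simultaneously crosslinked and bound, bound partners are binding
#' particles, per-particle bond counts within capacity, and positive radii.
#'
#' @param gel a `gel_system`.
#' @param capacity maximum concurrent particle bonds per particle.
#' @return The gel, invisibly; errors on any violation.
#' @export
audit_gel <- function(gel, capacity = 1L) {
  b <- gel$beads
  s <- gel$sites
  if (any(b$radius <= 0)) abort("audit: bead radius must be > 0")
  if (!all(s$bead %in% b$id[b$role == "end"]))
    abort("audit: binding sites must live on strand-end beads")
  if (!all(s$state %in% c("free", "crosslinked", "bound")))
    abort("audit: invalid site state")
  cl <- s[s$state == "crosslinked", ]
  if (nrow(cl)) {
    if (any(is.na(cl$partner))) abort("audit: crosslinked site lacks partner")
    back <- s$partner[match(cl$partner, s$bead)]
    if (any(is.na(back)) || any(back != cl$bead))
      abort("audit: crosslink partnership is not mutual")
    pstate <- s$state[match(cl$partner, s$bead)]
    if (any(pstate != "crosslinked"))
      abort("audit: a site is partnered with a non-crosslinked site")
    if ("species" %in% names(s)) {
      sp_a <- cl$species
      sp_b <- s$species[match(cl$partner, s$bead)]
      bad <- (!is.na(sp_a) | !is.na(sp_b)) &
        (is.na(sp_a) | is.na(sp_b) | sp_a == sp_b)
      if (any(bad)) abort("audit: non-complementary crosslink")
    }
  }
  bd <- s[s$state == "bound", ]
  if (nrow(bd)) {
    prole <- b$role[match(bd$partner, b$id)]
    pbind <- b$binding[match(bd$partner, b$id)]
    if (any(is.na(prole)) || any(prole != "particle") || !all(pbind))
      abort("audit: bound site must partner a binding particle")
    counts <- table(bd$partner)
    if (any(counts > capacity))
      abort("audit: particle binding capacity exceeded")
  }
  if (anyDuplicated(stats::na.omit(s$partner[s$state == "crosslinked"])))
    abort("audit: crosslink partner claimed twice")
  invisible(gel)
}
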