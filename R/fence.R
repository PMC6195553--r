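# Topological region classification for shell gels.
#
# The shell gel is free to drift and flex (stars have no cross-arm angular
# stiffness), so fixed lab-frame radii misclassify particles near a
# displaced fence.  The robust criterion is topological: a particle is
# interior if it lies inside the closed inner fence loop (the innermost
# circumferential chain of bonded beads), exterior if it lies outside the
# outer fence loop, and in the shell otherwise, with the loop polygons taken
# from the instantaneous bead positions of each frame.

#' Extract the closed fence loops of a square-ring shell
#'
#' Identifies, from the rest geometry of a freshly trimmed Chebyshev-metric
#' shell, the bead ids forming the innermost and outermost circumferential
#' fence chains, ordered around the loop.  The loops are fixed bead
#' sequences; their instantaneous positions define the classification
#' polygons at any later time.
#'
#' @param gel a trimmed, saturated `gel_system` (square-ring shell, at rest).
#' @param tol positional tolerance for assigning beads to a fence line.
#' @return List with integer vectors `inner` and `outer` (bead ids in loop
#'   order).
#' @export
fence_loops <- function(gel, tol = 0.3) {
  b <- gel$beads[gel$beads$role != "particle", , drop = FALSE]
  ctr <- gel$box / 2
  dx <- b$x - ctr[1]
  dy <- b$y - ctr[2]
  rcb <- pmax(abs(dx), abs(dy))
  cores <- b$role == "core"
  if (!any(cores)) abort("gel has no stars")
  r_in <- min(rcb[cores])
  r_out <- max(rcb[cores])
  loop_ids <- function(r) {
    on <- abs(rcb - r) < tol
    ids <- b$id[on]
    ang <- atan2(dy[on], dx[on])
    ids[order(ang)]
  }
  list(inner = loop_ids(r_in), outer = loop_ids(r_out))
}

# even-odd (ray casting) point-in-polygon, vectorized over points
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Classify particles against the instantaneous fence polygons
#'
#' For every sampled frame, classifies each tracked particle as `interior`
#' (inside the inner fence loop), `shell` (between the loops) or `exterior`
#' (outside the outer loop), using the unwrapped positions of the fence
#' beads at that frame.  Robust to drift and deformation of the gel.
#'
#' @param sim a `gel_sim` whose trajectory tracks both the particles and the
#'   fence-loop beads.
#' @param loops the [fence_loops()] of the initial gel.
#' @return Tibble with `time`, `binding`, `region`, `n` (zero-filled).
#' @export
count_fence_regions <- function(sim, loops) {
  traj <- sim$trajectory
  pids <- sim$gel$beads$id[sim$gel$beads$role == "particle"]
  times <- sort(unique(traj$time))
  idx <- split(seq_len(nrow(traj)), traj$time)
  rows <- vector("list", length(times))
  for (f in seq_along(times)) {
    fr <- traj[idx[[f]], , drop = FALSE]
    pos <- fr[match(c(loops$inner, loops$outer, pids), fr$bead), ,
              drop = FALSE]
    ni <- length(loops$inner)
    no <- length(loops$outer)
    vi <- pos[seq_len(ni), ]
    vo <- pos[ni + seq_len(no), ]
    pp <- pos[ni + no + seq_along(pids), ]
    ins_in <- point_in_polygon(pp$ux, pp$uy, vi$ux, vi$uy)
    ins_out <- point_in_polygon(pp$ux, pp$uy, vo$ux, vo$uy)
    region <- ifelse(ins_in, "interior", ifelse(ins_out, "shell", "exterior"))
    rows[[f]] <- tibble(time = times[f], bead = pids,
                        binding = pp$binding, region = region)
  }
  out <- bind_rows(rows) |>
    mutate(region = factor(.data$region,
                           levels = c("interior", "shell", "exterior"))) |>
    group_by(.data$time, .data$binding, .data$region) |>
    summarise(n = dplyr::n(), .groups = "drop")
  tidyr::complete(out, .data$time, .data$binding, .data$region,
                  fill = list(n = 0L))
}
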