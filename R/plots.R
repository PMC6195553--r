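# ggplot2 visualisations for the main result types

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_ribbon
#'   geom_segment geom_tile scale_x_log10 scale_y_log10 labs coord_equal
#'   facet_wrap theme_minimal
NULL

#' Plot a mean squared displacement curve
#'
#' Log-log MSD versus lag time with a standard-error ribbon; a plateau
#' signals caging, a unit slope the diffusive regime.
#'
#' @param object an `msd_result`.
#' @param ... ignored.
#' @return A ggplot.
#' @export
autoplot.msd_result <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[df$lag > 0, ]
  p <- ggplot(df, aes(x = .data$lag, y = .data$msd))
  if (any(is.finite(df$se)) && any(df$se > 0, na.rm = TRUE))
    p <- p + geom_ribbon(aes(ymin = pmax(.data$msd - .data$se, 1e-12),
                             ymax = .data$msd + .data$se), alpha = 0.25)
  p + geom_line() + scale_x_log10() + scale_y_log10() +
    labs(x = "lag time", y = "mean squared displacement") +
    theme_minimal()
}

#' @export
plot.msd_result <- function(x, ...) print(autoplot(x, ...))

#' Plot a gel configuration
#'
#' Beads drawn at their wrapped positions (2D only), permanent bonds and
#' crosslinks as segments, particles emphasised.
#'
#' @param object a `gel_system` with `d = 2`.
#' @param ... ignored.
#' @return A ggplot.
#' @export
autoplot.gel_system <- function(object, ...) {
  if (object$d != 2L) abort("gel plotting is 2D only")
  b <- object$beads
  seg <- function(pairs, kind) {
    if (!nrow(pairs)) return(NULL)
    tibble(x = b$x[match(pairs[[1]], b$id)],
           y = b$y[match(pairs[[1]], b$id)],
           xend = b$x[match(pairs[[2]], b$id)],
           yend = b$y[match(pairs[[2]], b$id)], kind = kind)
  }
  cl <- object$sites[object$sites$state == "crosslinked" &
                       object$sites$bead < object$sites$partner, ]
  segs <- bind_rows(seg(object$bonds[, c("i", "j")], "permanent"),
                    seg(cl[, c("bead", "partner")], "crosslink"))
  # drop segments that wrap around the periodic boundary (plot artefact)
  if (!is.null(segs) && nrow(segs)) {
    keep <- abs(segs$x - segs$xend) < object$box[1] / 2 &
      abs(segs$y - segs$yend) < object$box[2] / 2
    segs <- segs[keep, ]
  }
  p <- ggplot()
  if (!is.null(segs) && nrow(segs))
    p <- p + geom_segment(data = segs,
                          aes(x = .data$x, y = .data$y, xend = .data$xend,
                              yend = .data$yend, linetype = .data$kind),
                          linewidth = 0.3, colour = "darkgreen")
  p + geom_point(data = b,
                 aes(x = .data$x, y = .data$y, size = .data$radius,
                     colour = .data$role)) +
    ggplot2::scale_size_identity() + coord_equal() +
    labs(x = NULL, y = NULL) + theme_minimal()
}

#' @export
plot.gel_system <- function(x, ...) print(autoplot(x, ...))

#' Plot a high-affinity sweep
#'
#' Tile map of \eqn{D/D_0} over the state-energy difference and the exchange
#' barrier.
#'
#' @param object an `affinity_sweep`.
#' @param ... ignored.
#' @return A ggplot.
#' @export
autoplot.affinity_sweep <- function(object, ...) {
  ggplot(object, aes(x = .data$delta_E, y = .data$delta_T,
                     fill = .data$D_ratio)) +
    geom_tile() +
    labs(x = expression(E[b] - E[c]),
         y = expression(T[cb] - max(E[c], E[b])),
         fill = expression(D / D[0])) +
    theme_minimal()
}

#' @export
plot.affinity_sweep <- function(x, ...) print(autoplot(x, ...))

#' Plot shell-filter region counts over time
#'
#' @param object a `filter_demo`.
#' @param ... ignored.
#' @return A ggplot.
#' @export
autoplot.filter_demo <- function(object, ...) {
  df <- mutate(object$counts,
               type = ifelse(.data$binding, "binding", "non-binding"))
  ggplot(df, aes(x = .data$time, y = .data$n, colour = .data$region)) +
    geom_line() + facet_wrap(~type) +
    labs(x = "time", y = "particles") + theme_minimal()
}

#' @export
plot.filter_demo <- function(x, ...) print(autoplot(x, ...))
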