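# broom-style tidiers

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a diffusion fit
#'
#' @param x a `diffusion_fit`.
#' @param ... ignored.
#' @return One row per fitted quantity with estimate and standard error.
#' @export
tidy.diffusion_fit <- function(x, ...) {
  tibble(term = c("D", "slope", "intercept"),
         estimate = c(x$D, x$slope, x$intercept),
         std.error = c(x$se, x$se * 2 * x$d, NA_real_))
}

#' @rdname tidy.diffusion_fit
#' @export
glance.diffusion_fit <- function(x, ...) {
  tibble(D = x$D, se = x$se, r.squared = x$r_squared,
         window_min = x$window[1], window_max = x$window[2],
         n_series = x$n_series, d = x$d)
}

#' Tidy a tracer experiment
#'
#' @param x a `tracer_experiment`.
#' @param ... ignored.
#' @return The pooled MSD as a plain tibble (`tidy`), or a one-row summary
#'   with the fitted diffusion constant (`glance`).
#' @export
tidy.tracer_experiment <- function(x, ...) {
  out <- as_tibble(x$msd)
  out$binding <- x$binding
  out
}

#' @rdname tidy.tracer_experiment
#' @export
glance.tracer_experiment <- function(x, ...) {
  g <- glance(x$fit)
  g$binding <- x$binding
  g$replicates <- x$replicates
  g
}
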