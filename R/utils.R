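# internal helpers shared across modules

pos_cols <- function(d) c("x", "y", "z")[seq_len(d)]
upos_cols <- function(d) c("ux", "uy", "uz")[seq_len(d)]

# wrap coordinates into [0, L)
wrap_coord <- function(x, L) x - L * floor(x / L)

wrap_matrix <- function(m, box) {
  for (k in seq_along(box)) m[, k] <- wrap_coord(m[, k], box[k])
  m
}

# minimum-image displacement a - b (matrices or vectors)
min_image <- function(dx, box) {
  dx <- rbind(dx)
  for (k in seq_along(box)) {
    dx[, k] <- dx[, k] - box[k] * round(dx[, k] / box[k])
  }
  dx
}

# run code with a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# derive a distinct 31-bit sub-seed from a base seed and an index
sub_seed <- function(seed, index) {
  s <- (as.double(seed) * 48271 + as.double(index) * 16807 + 12345) %% 2147483647
  as.integer(s) + 1L
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort(sprintf("`%s` must be a single finite number", name))
  if (positive && x <= 0)
    abort(sprintf("`%s` must be > 0", name))
  invisible(x)
}
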