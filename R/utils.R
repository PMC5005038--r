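# Shared angle arithmetic and seed handling.

#' Wrap angles into [0, 360)
#'
#' @param x Angles in degrees.
#' @return Numeric vector of angles in `[0, 360)`.
#' @export
wrap_deg <- function(x) {
  x %% 360
}

#' Minimal absolute angular difference
#'
#' The wrapped difference between two angles, in `[0, 180]`. Symmetric in its
#' arguments and invariant to adding full turns to either.
#'
#' @param a,b Angles in degrees.
#' @return Numeric vector of differences in `[0, 180]`.
#' @export
delta_deg <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

# Snap angles to the nearest multiple of `step`, returning NA where the angle
# is not on the grid (within tol). Used when enumerating lattice directions.
snap_to_grid <- function(x, step = 30, tol = 1e-6) {
  s <- round(x / step) * step
  s[abs(x - s) > tol] <- NA_real_
  wrap_deg(s)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; when `seed`
# is NULL the current RNG stream is used (and advanced).
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    expr
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

# Derive `n` child seeds (< 2^31) from a parent seed, reproducibly.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopifnot_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min) {
    abort(sprintf("`%s` must be a single finite number >= %s.", name, format(min)))
  }
  invisible(x)
}
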