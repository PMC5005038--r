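# Planted signal models for synthetic voxel populations: six-fold (grid-like),
# one-fold (head-direction-like) and null tuning, plus mixtures.

#' Signal models for synthetic voxel populations
#'
#' Constructors for the per-region population tuning models used by
#' [simulate_trial_patterns()]:
#'
#' * `grid_model()`: every voxel shares the region's grid orientation `psi`
#'   (degrees, in `[0, 60)`); voxel `v` responds with
#'   `baseline_v + A_v * cos(6 * (theta - psi))`, the minimal population model
#'   producing 60-degree-periodic pattern similarity. Per-voxel amplitudes
#'   `A_v ~ N(0, amplitude_sd)` may be negative. When `orientation_deg` is
#'   `NULL` the orientation is drawn uniformly from `[0, 60)` at simulation
#'   time, mimicking idiosyncratic grid orientations across subjects.
#' * `hd_model()`: one-fold tuning around a per-voxel preferred direction
#'   `mu_v ~ U[0, 360)`; `tuning = "vonmises"` uses
#'   `gain_v * exp(kappa * (cos(theta - mu_v) - 1))`, `tuning = "cosine"` the
#'   pure cosine `gain_v * cos(theta - mu_v)` with `gain_v ~ N(0, gain_sd)`.
#' * `null_model()`: baseline plus noise only.
#' * `mixture_model()`: voxelwise mixture of the above in given proportions.
#'
#' All models add i.i.d. Gaussian noise with `noise_sd` per voxel and trial,
#' and per-voxel baselines `~ N(0, baseline_sd)`.
#'
#' @param orientation_deg Grid orientation `psi` in degrees (`[0, 60)`), or
#'   `NULL` to draw per simulation.
#' @param amplitude_sd Spread of per-voxel grid amplitudes.
#' @param baseline_sd Spread of per-voxel baselines.
#' @param noise_sd Trial-wise noise standard deviation (>= 0).
#' @param kappa Von Mises concentration of head-direction tuning (>= 0).
#' @param gain_sd Spread of per-voxel head-direction gains.
#' @param tuning `"vonmises"` or `"cosine"` tuning shape for `hd_model`.
#' @param components Named list of signal models for `mixture_model`.
#' @param weights Mixing proportions (summing to 1) for `mixture_model`.
#' @return A `signal_model` object.
#' @name signal_models
NULL

#' @rdname signal_models
#' @export
grid_model <- function(orientation_deg = NULL, amplitude_sd = 1,
                       baseline_sd = 1, noise_sd = 1) {
  if (!is.null(orientation_deg)) {
    stopifnot_scalar_number(orientation_deg, "orientation_deg", 0)
    if (orientation_deg >= 60) abort("`orientation_deg` must lie in [0, 60).")
  }
  stopifnot_scalar_number(noise_sd, "noise_sd", 0)
  structure(list(kind = "grid", orientation_deg = orientation_deg,
                 amplitude_sd = amplitude_sd, baseline_sd = baseline_sd,
                 noise_sd = noise_sd),
            class = "signal_model")
}

#' @rdname signal_models
#' @export
hd_model <- function(kappa = 2, gain_sd = 1, baseline_sd = 1, noise_sd = 1,
                     tuning = c("vonmises", "cosine")) {
  stopifnot_scalar_number(kappa, "kappa", 0)
  stopifnot_scalar_number(noise_sd, "noise_sd", 0)
  structure(list(kind = "hd", kappa = kappa, gain_sd = gain_sd,
                 baseline_sd = baseline_sd, noise_sd = noise_sd,
                 tuning = match.arg(tuning)),
            class = "signal_model")
}

#' @rdname signal_models
#' @export
null_model <- function(baseline_sd = 1, noise_sd = 1) {
  stopifnot_scalar_number(noise_sd, "noise_sd", 0)
  structure(list(kind = "null", baseline_sd = baseline_sd, noise_sd = noise_sd),
            class = "signal_model")
}

#' @rdname signal_models
#' @export
mixture_model <- function(components, weights) {
  if (length(components) != length(weights) || abs(sum(weights) - 1) > 1e-8) {
    abort("`weights` must match `components` and sum to 1.")
  }
  structure(list(kind = "mixture", components = components, weights = weights),
            class = "signal_model")
}

#' @export
print.signal_model <- function(x, ...) {
  cat("<signal_model>", x$kind, "\n")
  invisible(x)
}

# Mean tuning response per trial x voxel (no baseline, no noise).
tuning_response <- function(model, theta_deg, n_voxels) {
  th <- theta_deg * pi / 180
  switch(model$kind,
    grid = {
      psi <- model$orientation_deg %||% runif(1, 0, 60)
      amp <- rnorm(n_voxels, 0, model$amplitude_sd)
      outer(cos(6 * (th - psi * pi / 180)), amp)
    },
    hd = {
      mu <- runif(n_voxels, 0, 2 * pi)
      gain <- rnorm(n_voxels, 0, model$gain_sd)
      dd <- outer(th, mu, `-`)
      f <- if (model$tuning == "cosine") cos(dd) else exp(model$kappa * (cos(dd) - 1))
      sweep(f, 2L, gain, `*`)
    },
    null = matrix(0, length(theta_deg), n_voxels),
    abort("tuning_response is defined for grid/hd/null components only.")
  )
}

#' Simulate per-trial voxel patterns
#'
#' Generates a trials x voxels activity matrix for one region under a planted
#' signal model: the model's mean tuning response to each trial's sampled
#' direction, plus per-voxel baselines and i.i.d. Gaussian trial noise. With
#' zero noise and zero baseline spread, a grid model yields identical patterns
#' for trials whose directions differ by a multiple of 60 degrees and exactly
#' sign-flipped patterns for a 30-mod-60 difference.
#'
#' @param trials A trial tibble (uses `direction_deg`).
#' @param model A [signal_models] object.
#' @param n_voxels Number of voxels (>= 2).
#' @param seed Optional integer seed.
#' @param region,subject Optional identifiers carried in the result.
#' @return A `trial_pattern_set`: list with the `data` matrix and the trial
#'   metadata.
#' @export
simulate_trial_patterns <- function(trials, model, n_voxels, seed = NULL,
                                    region = NA_character_, subject = NA_integer_) {
  if (n_voxels < 2L) abort("`n_voxels` must be >= 2 (correlation undefined).")
  theta <- trials$direction_deg
  nt <- length(theta)
  with_seed(seed, {
    if (model$kind == "mixture") {
      counts <- as.vector(stats::rmultinom(1L, n_voxels, model$weights))
      parts <- purrr::map2(model$components, counts, function(m, k) {
        if (k == 0L) return(NULL)
        resp <- tuning_response(m, theta, k)
        base <- rnorm(k, 0, m$baseline_sd)
        noise <- matrix(rnorm(nt * k, 0, m$noise_sd), nt, k)
        sweep(resp, 2L, base, `+`) + noise
      })
      x <- do.call(cbind, purrr::compact(parts))
    } else {
      resp <- tuning_response(model, theta, n_voxels)
      base <- rnorm(n_voxels, 0, model$baseline_sd)
      noise <- matrix(rnorm(nt * n_voxels, 0, model$noise_sd), nt, n_voxels)
      x <- sweep(resp, 2L, base, `+`) + noise
    }
    trial_pattern_set(x, trials, region = region, subject = subject)
  })
}

#' Construct a trial pattern set
#'
#' @param data Trials x voxels numeric matrix.
#' @param trials Trial metadata tibble (one row per matrix row).
#' @param region,subject Optional identifiers.
#' @return A `trial_pattern_set`.
#' @export
trial_pattern_set <- function(data, trials, region = NA_character_,
                              subject = NA_integer_) {
  data <- as.matrix(data)
  if (nrow(data) != nrow(trials)) {
    abort("`data` must have one row per trial.")
  }
  structure(list(data = data, trials = trials, region = region,
                 subject = subject),
            class = "trial_pattern_set")
}

#' @export
print.trial_pattern_set <- function(x, ...) {
  cat(sprintf("<trial_pattern_set> %d trials x %d voxels (region %s)\n",
              nrow(x$data), ncol(x$data), x$region))
  invisible(x)
}

as_pattern_matrix <- function(patterns) {
  if (inherits(patterns, "trial_pattern_set")) patterns$data
  else as.matrix(patterns)
}
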