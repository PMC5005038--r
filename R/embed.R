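# Embedding trial patterns into a synthetic 4-D time series with drift, AR(1)
# noise and motion-correlated confounds.

#' Volume geometry with named masks
#'
#' A small volumetric geometry for the synthetic cohort: a 3-D shape, the
#' isotropic voxel size, and named binary masks (entorhinal-subregion-like
#' boxes, a parahippocampal-like box, and a gray-matter mask containing them).
#' All masks are synthetic stand-ins shaped like small anatomical ROIs; no
#' anatomical atlas is involved.
#'
#' @param shape Integer 3-vector of volume dimensions.
#' @param voxel_mm Isotropic voxel size in mm (default 2).
#' @param masks Named list of logical arrays of dimension `shape`; when
#'   omitted, default pmEC/alEC/PHG-like boxes and a gray-matter mask are
#'   built.
#' @return A `volume_geometry` list.
#' @export
volume_geometry <- function(shape = c(20L, 20L, 12L), voxel_mm = 2,
                            masks = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 4L)) {
    abort("`shape` must be three dimensions of at least 4 voxels.")
  }
  box <- function(xr, yr, zr) {
    m <- array(FALSE, shape)
    m[xr, yr, zr] <- TRUE
    m
  }
  if (is.null(masks)) {
    nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
    zmid <- max(1L, nz %/% 2 - 1L):min(nz, nz %/% 2 + 1L)
    masks <- list(
      pmEC_left  = box(2:5, 2:6, zmid),
      pmEC_right = box((nx - 4):(nx - 1), 2:6, zmid),
      alEC_left  = box(2:5, (ny - 5):(ny - 1), zmid),
      alEC_right = box((nx - 4):(nx - 1), (ny - 5):(ny - 1), zmid),
      PHG        = box((nx %/% 2 - 2):(nx %/% 2 + 2), 2:6, zmid)
    )
    gm <- array(FALSE, shape)
    gm[2:(nx - 1), 2:(ny - 1), 2:(nz - 1)] <- TRUE
    masks$graymatter <- gm
  }
  for (nm in names(masks)) {
    if (!identical(dim(masks[[nm]]), shape)) {
      abort(sprintf("mask '%s' does not fit the volume shape.", nm))
    }
  }
  structure(list(shape = shape, voxel_mm = voxel_mm, masks = masks),
            class = "volume_geometry")
}

#' Acquisition and noise parameters for time-series embedding
#'
#' @param tr Repetition time in seconds (default 1.8).
#' @param drift_amplitude Amplitude of the low-frequency cosine drift.
#' @param drift_period_s Drift period in seconds.
#' @param ar_coef AR(1) coefficient of the temporal noise.
#' @param noise_sd Innovation standard deviation of the temporal noise.
#' @param motion_sd Step size of the random-walk motion time courses.
#' @param motion_loading_sd Spread of per-voxel motion loadings (0 disables
#'   motion confounds).
#' @param pad_s Seconds of scan appended after the last trial window.
#' @return An `acquisition_params` list.
#' @export
acquisition_params <- function(tr = 1.8, drift_amplitude = 1,
                               drift_period_s = 150, ar_coef = 0.3,
                               noise_sd = 1, motion_sd = 0.05,
                               motion_loading_sd = 0.5, pad_s = 16) {
  stopifnot_scalar_number(tr, "tr", .Machine$double.eps)
  if (any(c(drift_amplitude, ar_coef, noise_sd, motion_sd,
            motion_loading_sd, pad_s) < 0) || ar_coef >= 1) {
    abort("noise parameters must be non-negative and `ar_coef` < 1.")
  }
  list(tr = tr, drift_amplitude = drift_amplitude,
       drift_period_s = drift_period_s, ar_coef = ar_coef,
       noise_sd = noise_sd, motion_sd = motion_sd,
       motion_loading_sd = motion_loading_sd, pad_s = pad_s)
}

# Canonical double-gamma hemodynamic response sampled at dt.
hrf_double_gamma <- function(t) {
  pos <- stats::dgamma(t, shape = 6, rate = 1)
  und <- stats::dgamma(t, shape = 16, rate = 1) / 6
  pos - und
}

#' Embed trial patterns into a 4-D run
#'
#' Injects the per-trial voxel patterns into the mask voxels of a synthetic
#' run: each trial contributes its pattern scaled by a boxcar over the cue +
#' imagination period convolved with a canonical double-gamma hemodynamic
#' response, sampled at the volume times. Low-frequency cosine drift, AR(1)
#' noise and motion-loading x motion-time-course confounds are added over the
#' whole volume, and the 6-column motion table is returned for the nuisance
#' GLM.
#'
#' @param patterns A `trial_pattern_set` whose rows match `trials`.
#' @param trials Trial tibble for one run (block); onsets are run-relative.
#' @param geometry A [volume_geometry()].
#' @param acquisition An [acquisition_params()].
#' @param mask Name of the mask in `geometry$masks` receiving the signal.
#' @param seed Optional integer seed.
#' @return A list: `data` (4-D array x,y,z,time), `motion` (tibble, 6
#'   columns), `tr`, `frame_times`.
#' @export
embed_timeseries <- function(patterns, trials, geometry, acquisition,
                             mask = "pmEC_left", seed = NULL) {
  x <- as_pattern_matrix(patterns)
  if (nrow(x) != nrow(trials)) abort("`patterns` rows must match `trials`.")
  m <- geometry$masks[[mask]]
  if (is.null(m)) abort(sprintf("unknown mask '%s'.", mask))
  vox <- which(m)
  if (length(vox) == 0L) abort(sprintf("mask '%s' is empty.", mask))
  if (ncol(x) != length(vox)) {
    abort(sprintf("patterns have %d voxels but mask '%s' has %d.",
                  ncol(x), mask, length(vox)))
  }
  tr <- acquisition$tr
  run_end <- max(trials$imagination_end_s) + acquisition$pad_s
  n_vols <- ceiling(run_end / tr) + 1L
  if (any(floor(trials$imagination_end_s / tr) + 3L > n_vols)) {
    abort("trial onsets do not fit within the generated volume count.")
  }
  if (any(diff(sort(trials$cue_onset_s)) < 1e-9)) {
    warn("overlapping analysis windows: coincident trial onsets.")
  }
  # trial regressors: boxcar over cue + imagination, HRF-convolved, at TR grid
  dt <- 0.1
  tgrid <- seq(0, n_vols * tr + 32, by = dt)
  h <- hrf_double_gamma(seq(0, 32, by = dt))
  frame_times <- (seq_len(n_vols) - 1L) * tr
  reg <- vapply(seq_len(nrow(trials)), function(k) {
    neural <- as.numeric(tgrid >= trials$cue_onset_s[k] &
                           tgrid < trials$imagination_end_s[k])
    bold <- convolve(neural, rev(h), type = "open")[seq_along(tgrid)] * dt
    stats::approx(tgrid, bold, xout = frame_times, rule = 2)$y
  }, numeric(n_vols))

  n_total <- prod(geometry$shape)
  with_seed(seed, {
    gm <- geometry$masks$graymatter
    active <- if (is.null(gm)) seq_len(n_total) else which(gm | m)
    ts <- matrix(0, n_vols, n_total)
    innov <- matrix(rnorm(n_vols * length(active), 0, acquisition$noise_sd),
                    n_vols, length(active))
    if (acquisition$ar_coef > 0) {
      innov <- apply(innov, 2L, function(e) {
        as.numeric(stats::filter(e, acquisition$ar_coef, method = "recursive"))
      })
    }
    ts[, active] <- innov
    if (acquisition$drift_amplitude > 0) {
      phase <- runif(length(active), 0, 2 * pi)
      drift <- acquisition$drift_amplitude *
        cos(outer(2 * pi * frame_times / acquisition$drift_period_s,
                  phase, `+`))
      ts[, active] <- ts[, active] + drift
    }
    motion <- matrix(rnorm(n_vols * 6L, 0, acquisition$motion_sd), n_vols, 6L)
    motion <- apply(motion, 2L, cumsum)
    colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")
    if (acquisition$motion_loading_sd > 0) {
      load <- matrix(rnorm(6L * length(active), 0, acquisition$motion_loading_sd),
                     6L, length(active))
      ts[, active] <- ts[, active] + motion %*% load
    }
    ts[, vox] <- ts[, vox] + reg %*% x
    list(
      data = array(t(ts), dim = c(geometry$shape, n_vols)),
      motion = as_tibble(as.data.frame(motion)),
      tr = tr,
      frame_times = frame_times
    )
  })
}

#' Extract the time x voxels matrix of a mask from a 4-D array
#'
#' @param volume4d A 4-D array (x, y, z, time).
#' @param mask Logical 3-D array of matching spatial dimensions.
#' @return A time x voxels matrix.
#' @export
ts_matrix <- function(volume4d, mask) {
  d <- dim(volume4d)
  if (!identical(dim(mask), d[1:3])) abort("mask does not match volume geometry.")
  mat <- matrix(volume4d, prod(d[1:3]), d[4])
  t(mat[which(mask), , drop = FALSE])
}
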