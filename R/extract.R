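# Pattern extraction: nuisance-GLM residualization, high-pass filtering,
# trial-window averaging and tSNR.

#' Build a nuisance regressor model
#'
#' Combines the six motion columns with an intercept (and optionally a
#' discrete-cosine high-pass basis) into the design matrix whose least-squares
#' residuals feed the similarity analysis.
#'
#' @param motion A matrix or tibble with 6 motion columns (one row per
#'   volume).
#' @param highpass_basis Optional extra basis columns (e.g. from
#'   [dct_basis()]).
#' @param intercept Include an intercept column (default `TRUE`).
#' @return A numeric design matrix of full column rank.
#' @export
nuisance_model <- function(motion, highpass_basis = NULL, intercept = TRUE) {
  x <- as.matrix(motion)
  if (ncol(x) != 6L) abort("`motion` must have exactly 6 columns.")
  cols <- list(if (intercept) matrix(1, nrow(x), 1,
                                     dimnames = list(NULL, "intercept")),
               x, highpass_basis)
  xm <- do.call(cbind, purrr::compact(cols))
  check_full_rank(xm)
  xm
}

check_full_rank <- function(x) {
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    bad <- colnames(x)[qx$pivot[(qx$rank + 1L):ncol(x)]] %||% "unnamed"
    abort(paste0("rank-deficient nuisance regressors; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }
  invisible(qx)
}

#' Residualize a time series against nuisance regressors
#'
#' Per-voxel ordinary least squares of the time series on the nuisance design
#' matrix; returns the residuals, which are exactly orthogonal to every
#' regressor column. The operation is idempotent.
#'
#' @param timeseries Time x voxels numeric matrix.
#' @param nuisance Design matrix from [nuisance_model()] (or any full-rank
#'   matrix with matching rows).
#' @return The residual time x voxels matrix.
#' @export
residualize_nuisance <- function(timeseries, nuisance) {
  timeseries <- as.matrix(timeseries)
  nuisance <- as.matrix(nuisance)
  if (nrow(timeseries) != nrow(nuisance)) {
    abort("`timeseries` and `nuisance` must have the same number of rows.")
  }
  qx <- check_full_rank(nuisance)
  qr.resid(qx, timeseries)
}

#' Discrete-cosine high-pass basis
#'
#' The DCT components with period longer than `cutoff_s`, the drift terms
#' removed by [highpass_filter()].
#'
#' @param n_vols Number of volumes.
#' @param tr Repetition time in seconds.
#' @param cutoff_s High-pass cutoff period in seconds.
#' @return Matrix of basis columns (possibly zero columns).
#' @export
dct_basis <- function(n_vols, tr, cutoff_s = 100) {
  n_comp <- floor(2 * n_vols * tr / cutoff_s)
  if (n_comp < 1L) return(matrix(numeric(0), n_vols, 0))
  t_idx <- seq_len(n_vols) - 0.5
  b <- sapply(seq_len(n_comp), function(k) cos(pi * k * t_idx / n_vols))
  colnames(b) <- paste0("dct", seq_len(n_comp))
  b
}

#' High-pass filter a time series
#'
#' Removes fluctuations slower than the cutoff period by projecting out a
#' discrete-cosine drift basis (plus the mean). A 100 s cutoff attenuates a
#' 200 s cosine to near zero while preserving a 20 s cosine.
#'
#' @param timeseries Time x voxels matrix.
#' @param tr Repetition time in seconds.
#' @param cutoff_s Cutoff period in seconds; must be finite and `> 2 * tr`.
#' @return Filtered matrix of the same shape.
#' @export
highpass_filter <- function(timeseries, tr, cutoff_s = 100) {
  if (!is.finite(cutoff_s) || cutoff_s <= 2 * tr) {
    abort("`cutoff_s` must be finite and greater than 2 * tr.")
  }
  timeseries <- as.matrix(timeseries)
  basis <- cbind(1, dct_basis(nrow(timeseries), tr, cutoff_s))
  qr.resid(qr(basis), timeseries)
}

#' Extract per-trial patterns from a run's time series
#'
#' Averages, for every trial, the volume during which the imagination period
#' ended and the two following volumes (the analysis window covering the late
#' BOLD response of the imagination period). Volume `k` (0-based) is taken to
#' cover acquisition time `[k * tr, (k + 1) * tr)`, so the window starts at
#' `floor(end_time / tr)`; with `window_rule = "cue_onset"` the window is
#' locked to `floor(cue_onset / tr)` instead.
#'
#' @param timeseries Time x voxels matrix for one run (typically
#'   residualized).
#' @param trials Trial tibble for that run (uses `imagination_end_s` or
#'   `cue_onset_s`).
#' @param tr Repetition time in seconds.
#' @param window_rule `"imagination_end"` (default) or `"cue_onset"`.
#' @param n_window Number of volumes averaged (default 3).
#' @return A `trial_pattern_set` for the run.
#' @export
extract_trial_patterns <- function(timeseries, trials, tr,
                                   window_rule = c("imagination_end", "cue_onset"),
                                   n_window = 3L) {
  window_rule <- match.arg(window_rule)
  timeseries <- as.matrix(timeseries)
  anchor <- switch(window_rule,
    imagination_end = trials$imagination_end_s,
    cue_onset = trials$cue_onset_s
  )
  first <- floor(anchor / tr) # 0-based volume index
  last <- first + n_window - 1L
  over <- which(last + 1L > nrow(timeseries))
  if (length(over) > 0) {
    abort(paste0("analysis window exceeds run length for trial(s): ",
                 paste(trials$trial_id[over], collapse = ", ")))
  }
  x <- t(vapply(first, function(f) {
    colMeans(timeseries[(f + 1L):(f + n_window), , drop = FALSE])
  }, numeric(ncol(timeseries))))
  trial_pattern_set(x, trials)
}

#' Temporal signal-to-noise ratio
#'
#' The mean over time of the region-mean signal divided by its temporal
#' standard deviation. Defined on the region-mean time course;
#' `voxelwise = TRUE` instead averages voxelwise tSNR values. Zero temporal
#' variance yields `NA` (undefined), not infinity.
#'
#' @param timeseries Time x voxels matrix (already restricted to the region).
#' @param voxelwise Average per-voxel tSNR instead of the region-mean course.
#' @return A tibble with `tsnr` and an `undefined` flag.
#' @export
compute_tsnr <- function(timeseries, voxelwise = FALSE) {
  timeseries <- as.matrix(timeseries)
  if (nrow(timeseries) < 2L) abort("need at least 2 volumes.")
  one <- function(m) {
    s <- sd(m)
    if (s == 0) NA_real_ else mean(m) / s
  }
  val <- if (voxelwise) {
    mean(apply(timeseries, 2L, one))
  } else {
    one(rowMeans(timeseries))
  }
  tibble(tsnr = val, undefined = is.na(val))
}
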