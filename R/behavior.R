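# Behavioral error statistics: chance testing, the behavioral 60-degree
# modulation control, accuracy correlations and map-test scoring.

#' Absolute wrapped angular error
#'
#' `min(|a - b| mod 360, 360 - |a - b| mod 360)`, the minimal angular distance
#' between the correct and the indicated direction, in `[0, 180]`.
#'
#' @param true_deg,response_deg Angles in degrees.
#' @return Error in degrees.
#' @export
angular_error <- function(true_deg, response_deg) {
  delta_deg(true_deg, response_deg)
}

#' Chance-performance exclusion test
#'
#' One-sided Wilcoxon signed-rank test of a subject's absolute angular errors
#' against the 90-degree chance median (a uniform-random responder's errors
#' are uniform on `[0, 180]`). Subjects whose median error is not
#' significantly smaller than 90 degrees are flagged for exclusion.
#'
#' @param errors Absolute angular errors in `[0, 180]`, at least 6 values.
#' @param alpha Significance level for the exclusion decision.
#' @return A tibble with the test statistic, p-value, `degenerate` flag (all
#'   errors identical), and the `exclude` decision.
#' @export
chance_performance_test <- function(errors, alpha = 0.05) {
  if (length(errors) < 6L) abort("need at least 6 errors.")
  degenerate <- diff(range(errors)) == 0
  if (degenerate && errors[1] == 90) {
    return(tibble(statistic = NA_real_, p_value = 1, degenerate = TRUE,
                  exclude = TRUE))
  }
  wt <- suppressWarnings(wilcox.test(errors, mu = 90, alternative = "less"))
  tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
         degenerate = degenerate, exclude = wt$p.value >= alpha)
}

#' Behavioral 60-degree modulation contrast
#'
#' Combines performance over trial pairs by multiplying the two trials'
#' absolute angular errors and contrasts the mean combined error between the
#' 0-mod-60 and the 30-mod-60 condition. Under direction-independent errors
#' the expected contrast is zero; at the group level the per-subject
#' differences are tested against 0 with a one-sample t-test.
#'
#' @param errors Per-trial absolute angular errors, aligned with the trial
#'   enumeration in `labels` (trial ids 1..n). Missing responses (`NA`) drop
#'   the affected pairs.
#' @param labels Pair labels from [label_pairs()].
#' @return A `contrast_result` on the combined-error scale.
#' @export
combined_error_contrast <- function(errors, labels) {
  combined <- errors[labels$i] * errors[labels$j]
  ok <- !is.na(combined)
  if (any(!ok)) {
    rlang::inform(sprintf("dropping %d pairs with missing responses.", sum(!ok)))
  }
  a <- ok & labels$rem60 == 0
  b <- ok & labels$rem60 == 30
  if (!any(a) || !any(b)) abort("empty condition in combined-error contrast.")
  mean_a <- mean(combined[a]); mean_b <- mean(combined[b])
  structure(
    list(scheme = "behavior_mod60", exclude = character(),
         mean_a = mean_a, mean_b = mean_b, difference = mean_a - mean_b,
         n_a = sum(a), n_b = sum(b), n_excluded = sum(!ok)),
    class = "contrast_result"
  )
}

#' Correlate imagination accuracy with training and map-test performance
#'
#' Accuracy is defined as `pi` minus the mean absolute angular error in
#' radians, so a perfect performer scores `pi` and a chance performer about
#' `pi/2`. Pearson correlations of accuracy with navigation success (number
#' of buildings found), training direction accuracy and (z-scored, negated)
#' map-test error are reported, together with partial correlations
#' controlling for training time when a `training_time` column is present.
#'
#' @param subjects A tibble with one row per subject: `mean_error_deg` plus
#'   any of `buildings_found`, `training_error_deg`, `map_error`,
#'   `training_time`.
#' @return A tibble: `term`, `r`, `p_value`, `partial_r`, `partial_p`.
#' @export
accuracy_correlations <- function(subjects) {
  if (nrow(subjects) < 3L) abort("need at least 3 subjects.")
  acc <- pi - subjects$mean_error_deg * pi / 180
  covars <- list(
    buildings_found = subjects$buildings_found,
    training_accuracy = if (!is.null(subjects$training_error_deg)) {
      pi - subjects$training_error_deg * pi / 180
    },
    map_test = if (!is.null(subjects$map_error)) {
      -as.vector(scale(subjects$map_error))
    }
  )
  covars <- purrr::compact(covars)
  ttime <- subjects$training_time
  purrr::imap_dfr(covars, function(v, nm) {
    if (sd(v) == 0) abort(sprintf("zero-variance covariate '%s'.", nm))
    ct <- stats::cor.test(acc, v)
    out <- tibble(term = nm, r = unname(ct$estimate), p_value = ct$p.value,
                  partial_r = NA_real_, partial_p = NA_real_)
    if (!is.null(ttime)) {
      ra <- resid(lm(acc ~ ttime)); rv <- resid(lm(v ~ ttime))
      pt_ <- stats::cor.test(ra, rv)
      out$partial_r <- unname(pt_$estimate)
      out$partial_p <- pt_$p.value
    }
    out
  })
}

#' Map-test placement error
#'
#' Euclidean distance between the correct building location on the map and
#' the location the subject indicated.
#'
#' @param true_xy,placed_xy Two-column matrices (or data frames) of map
#'   coordinates.
#' @return Distances, one per row.
#' @export
map_test_score <- function(true_xy, placed_xy) {
  true_xy <- as.matrix(true_xy); placed_xy <- as.matrix(placed_xy)
  sqrt(rowSums((true_xy - placed_xy)^2))
}
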