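# Core representational similarity: pairwise Pearson/Fisher-z similarity,
# condition contrasts, exclusion filters and distance residualization.

# atanh(1) is infinite; noiseless synthetic patterns do reach r = +/-1, so z
# is capped there and the pair flagged.
Z_CAP <- atanh(1 - 1e-15)

fisher_z <- function(r) {
  pmin(pmax(atanh(pmin(pmax(r, -1), 1)), -Z_CAP), Z_CAP)
}

#' Pairwise pattern similarity
#'
#' Pearson correlation across voxels for every unordered pair of trials, with
#' the Fisher z transform `atanh(r)` applied for averaging and testing. Pairs
#' involving a zero-variance (constant) pattern are flagged invalid and are
#' excluded from condition means downstream; correlations of exactly +/-1 are
#' capped at `atanh(1 - 1e-15)` and flagged.
#'
#' @param patterns A trials x voxels numeric matrix, or a `trial_pattern_set`.
#' @return A tibble with one row per unordered pair (same enumeration as
#'   [label_pairs()]): `i`, `j`, `r`, `z`, `valid`, `capped`.
#' @export
pairwise_similarity <- function(patterns) {
  x <- as_pattern_matrix(patterns)
  if (ncol(x) < 2L) abort("need at least 2 voxels to correlate patterns.")
  if (nrow(x) < 2L) abort("need at least 2 trials to form pairs.")
  n <- nrow(x)
  sds <- apply(x, 1L, sd)
  cmat <- suppressWarnings(cor(t(x)))
  idx <- which(upper.tri(cmat), arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  r <- cmat[idx]
  valid <- sds[i] > 0 & sds[j] > 0 & !is.na(r)
  tibble(
    i = i, j = j, r = r,
    z = ifelse(valid, fisher_z(r), NA_real_),
    valid = valid,
    capped = valid & abs(r) >= 1 - 1e-15
  )
}

known_exclusions <- c("same_start", "same_target", "same_combo", "same_block",
                      "both_inner_target", "both_ns_street")

#' Select trial pairs by exclusion filters
#'
#' Combines the requested pair-exclusion flags into a keep mask: a pair is
#' dropped when any requested flag is `TRUE` for it. Recognized exclusions are
#' `"same_start"`, `"same_target"`, `"same_combo"`, `"same_block"`,
#' `"both_inner_target"` and `"both_ns_street"`.
#'
#' @param labels A pair-label tibble from [label_pairs()].
#' @param exclusions Character vector of exclusion names (possibly empty).
#' @return A logical keep vector, one element per pair.
#' @export
filter_pairs <- function(labels, exclusions = character()) {
  bad <- setdiff(exclusions, known_exclusions)
  if (length(bad) > 0) {
    abort(paste0("unknown exclusion name(s): ", paste(bad, collapse = ", "),
                 ". Known: ", paste(known_exclusions, collapse = ", "), "."))
  }
  keep <- rep(TRUE, nrow(labels))
  for (e in exclusions) keep <- keep & !labels[[e]]
  keep
}

# Condition membership (A, B) per scheme; returns list of logical vectors.
condition_membership <- function(labels, scheme) {
  switch(scheme,
    onefold = list(a = labels$delta_deg <= 30, b = labels$delta_deg >= 60),
    mod60 = list(a = labels$rem60 == 0, b = labels$rem60 == 30),
    mod90 = list(a = labels$rem90 == 0, b = labels$rem90 %in% c(30, 60)),
    cardinal = list(a = labels$both_cardinal, b = !labels$both_cardinal),
    abort(sprintf("unknown contrast scheme '%s'.", scheme))
  )
}

#' Condition contrast of mean pattern similarity
#'
#' Averages Fisher-z similarity within two pair conditions and returns the
#' difference A - B. Schemes: `"onefold"` (similar directions, delta <= 30,
#' against dissimilar, delta >= 60), `"mod60"` (angular difference a multiple
#' of 60 against remainder 30, the hexadirectional grid contrast), `"mod90"`
#' (four-fold control: remainder 0 mod 90 against 30 or 60), and `"cardinal"`
#' (both trials sampling a cardinal direction against the rest). Condition
#' means are unweighted means over the included valid pairs.
#'
#' @param sim A similarity tibble from [pairwise_similarity()].
#' @param labels Pair labels from [label_pairs()] (same pair enumeration).
#' @param scheme One of `"onefold"`, `"mod60"`, `"mod90"`, `"cardinal"`.
#' @param exclude Exclusion filter names passed to [filter_pairs()].
#' @return A `contrast_result`: mean z per condition, the difference, and
#'   pair counts. Has [tidy()] and [glance()] methods.
#' @export
condition_contrast <- function(sim, labels, scheme = "mod60",
                               exclude = character()) {
  if (nrow(sim) != nrow(labels)) {
    abort("`sim` and `labels` must enumerate the same pairs.")
  }
  keep <- filter_pairs(labels, exclude) & sim$valid
  mem <- condition_membership(labels, scheme)
  a <- keep & mem$a
  b <- keep & mem$b
  if (!any(a) || !any(b)) {
    abort(sprintf(
      "empty condition after filtering (scheme '%s', exclusions: %s).",
      scheme, if (length(exclude)) paste(exclude, collapse = ", ") else "none"
    ))
  }
  mean_a <- mean(sim$z[a])
  mean_b <- mean(sim$z[b])
  structure(
    list(scheme = scheme, exclude = exclude,
         mean_a = mean_a, mean_b = mean_b,
         difference = mean_a - mean_b,
         n_a = sum(a), n_b = sum(b),
         n_excluded = sum(!keep)),
    class = "contrast_result"
  )
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf(
    "<contrast_result> scheme %s: mean z A = %.4f (n = %d), B = %.4f (n = %d), difference = %.4f\n",
    x$scheme, x$mean_a, x$n_a, x$mean_b, x$n_b, x$difference))
  if (length(x$exclude)) cat("  excluded pairs:", paste(x$exclude, collapse = ", "), "\n")
  invisible(x)
}

#' Residualize pattern similarity on a pair distance measure
#'
#' Regresses pairwise Fisher-z similarity on an intercept plus one of the
#' three pair distance measures (continuous, or split at the median into a
#' binary high/low predictor) and returns the similarity table with `z`
#' replaced by the regression residuals, for distance-controlled contrasts.
#'
#' @param sim Similarity tibble from [pairwise_similarity()].
#' @param labels Pair labels from [label_pairs()].
#' @param measure `"mean"` (I: mean vector length), `"absdiff"` (II: absolute
#'   length difference) or `"neighborhood"` (III: mean distance between all
#'   four buildings).
#' @param binary Use a median-split binary predictor instead of the
#'   continuous measure.
#' @return The similarity tibble with residualized `z` for valid pairs.
#' @export
residualize_distance <- function(sim, labels,
                                 measure = c("mean", "absdiff", "neighborhood"),
                                 binary = FALSE) {
  measure <- match.arg(measure)
  if (nrow(sim) != nrow(labels)) {
    abort("`sim` and `labels` must enumerate the same pairs.")
  }
  pred <- labels[[paste0("dist_", measure)]]
  if (binary) {
    if (diff(range(pred)) == 0) {
      abort("constant distance predictor: binary median split undefined.")
    }
    pred <- as.numeric(pred > median(pred))
  }
  ok <- sim$valid
  fit <- lm(sim$z[ok] ~ pred[ok])
  sim$z[ok] <- resid(fit)
  sim
}
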