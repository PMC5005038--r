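# broom-style tidiers for the result objects.

#' Tidy a condition contrast
#'
#' @param x A `contrast_result`.
#' @param ... Unused.
#' @return One row per condition: `condition`, `mean_z`, `n_pairs`.
#' @method tidy contrast_result
#' @export
tidy.contrast_result <- function(x, ...) {
  tibble(
    condition = c("A", "B"),
    mean_z = c(x$mean_a, x$mean_b),
    n_pairs = c(x$n_a, x$n_b)
  )
}

#' @rdname tidy.contrast_result
#' @method glance contrast_result
#' @export
glance.contrast_result <- function(x, ...) {
  tibble(scheme = x$scheme, difference = x$difference,
         n_a = x$n_a, n_b = x$n_b, n_excluded = x$n_excluded)
}

#' Tidy a subject-level permutation test
#'
#' @param x A `permutation_result`.
#' @param ... Unused.
#' @method tidy permutation_result
#' @export
tidy.permutation_result <- function(x, ...) {
  tibble(scheme = x$scheme, observed = x$observed, p_value = x$p, z = x$z,
         n_perm = x$n_perm, tail = x$tail)
}

#' @rdname tidy.permutation_result
#' @method glance permutation_result
#' @export
glance.permutation_result <- function(x, ...) {
  tibble(p_value = x$p, z = x$z, null_mean = x$null_mean, null_sd = x$null_sd)
}

#' Tidy a group-level test
#'
#' @param x A `group_result`.
#' @param ... Unused.
#' @method tidy group_result
#' @export
tidy.group_result <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p,
         p_uncorrected = x$p_uncorrected, mean = x$mean,
         cohens_d = x$cohens_d, method = x$method, correction = x$correction)
}

#' @rdname tidy.group_result
#' @method glance group_result
#' @export
glance.group_result <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p, n = x$n)
}
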