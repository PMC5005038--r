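# Subject-level permutation testing and group-level parametric / permutation
# inference.

#' Subject-level permutation test of a condition contrast
#'
#' Tests a subject's observed contrast against a null distribution obtained by
#' shuffling the trial labels: each permutation reassigns the trial metadata
#' (direction, start, target, block) across trials, relabels every pair
#' consistently (conditions, filters and distances move together), and
#' recomputes the contrast on the unchanged correlation matrix. The p-value
#' uses the add-one estimator `p = (1 + #[perm >= observed]) / (n_perm + 1)`,
#' so it is never exactly zero, and is converted to a signed z-statistic
#' `qnorm(1 - p)`.
#'
#' @param sim Similarity tibble from [pairwise_similarity()].
#' @param labels Pair labels from [label_pairs()] (same pair enumeration).
#' @param scheme Contrast scheme (see [condition_contrast()]).
#' @param exclude Exclusion filters applied throughout.
#' @param n_perm Number of permutations (>= 100; default 10000).
#' @param seed Optional integer seed.
#' @param tail `"greater"` (default; larger contrast is evidence) or
#'   `"two.sided"`.
#' @return A `permutation_result` with the observed contrast, `p`, `z` and the
#'   permutation count. Has [tidy()]/[glance()] methods.
#' @export
permutation_test_subject <- function(sim, labels, scheme = "mod60",
                                     exclude = character(), n_perm = 10000L,
                                     seed = NULL, tail = c("greater", "two.sided")) {
  tail <- match.arg(tail)
  if (n_perm < 100L) abort("`n_perm` must be at least 100.")
  obs <- condition_contrast(sim, labels, scheme, exclude)$difference

  n <- max(labels$j)
  # pair row lookup: K[a, b] = K[b, a] = row index of unordered pair (a, b)
  K <- matrix(0L, n, n)
  K[cbind(labels$i, labels$j)] <- seq_len(nrow(labels))
  K[cbind(labels$j, labels$i)] <- seq_len(nrow(labels))

  mem <- condition_membership(labels, scheme)
  keep_lab <- filter_pairs(labels, exclude)
  # z stays with the physical pair; validity is a property of the data
  ok <- sim$valid
  z <- sim$z[ok]
  li <- labels$i[ok]
  lj <- labels$j[ok]
  in_a <- mem$a & keep_lab
  in_b <- mem$b & keep_lab
  if (!any(in_a) || !any(in_b)) {
    abort("degenerate labels: a condition is empty (single direction?).")
  }

  with_seed(seed, {
    perm_stats <- vapply(seq_len(n_perm), function(p) {
      prm <- sample.int(n)
      idx <- K[cbind(prm[li], prm[lj])]
      a <- in_a[idx]
      b <- in_b[idx]
      sum(z[a]) / sum(a) - sum(z[b]) / sum(b)
    }, numeric(1))
    stat_obs <- if (tail == "two.sided") abs(obs) else obs
    stat_perm <- if (tail == "two.sided") abs(perm_stats) else perm_stats
    p <- (1 + sum(stat_perm >= stat_obs)) / (n_perm + 1)
    structure(
      list(observed = obs, n_perm = n_perm, p = p, z = qnorm(1 - p),
           tail = tail, scheme = scheme,
           null_mean = mean(perm_stats), null_sd = sd(perm_stats)),
      class = "permutation_result"
    )
  })
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> %s: observed = %.4f, p = %.4g (%d perms), z = %.3f\n",
    x$scheme, x$observed, x$p, x$n_perm, x$z))
  invisible(x)
}

#' Group-level one-sample t-test
#'
#' Standard one-sample t-test of per-subject values (contrast differences or
#' permutation z-statistics) against zero, optionally one-tailed, with a
#' Bonferroni factor for multiple region comparisons (p multiplied by
#' `correction_k`, capped at 1).
#'
#' @param values Per-subject values.
#' @param tail `"greater"`, `"two.sided"` or `"less"`.
#' @param correction_k Bonferroni multiplier (e.g. 2 for left/right).
#' @return A `group_result` with `statistic`, `df`, `p`, the correction and
#'   Cohen's d. Has [tidy()]/[glance()] methods.
#' @export
group_one_sample_t <- function(values, tail = c("greater", "two.sided", "less"),
                               correction_k = 1) {
  tail <- match.arg(tail)
  n <- length(values)
  if (n < 2L) abort("need at least 2 values.")
  s <- sd(values)
  if (s == 0) abort("zero variance: t statistic undefined.")
  m <- mean(values)
  tstat <- m / (s / sqrt(n))
  df <- n - 1L
  p_raw <- switch(tail,
    greater = pt(tstat, df, lower.tail = FALSE),
    less = pt(tstat, df),
    two.sided = 2 * pt(abs(tstat), df, lower.tail = FALSE)
  )
  structure(
    list(statistic = tstat, df = df, p = min(1, p_raw * correction_k),
         p_uncorrected = p_raw, tail = tail,
         correction = if (correction_k > 1) sprintf("bonferroni x%g", correction_k) else "none",
         mean = m, sd = s, n = n, cohens_d = m / s, method = "parametric"),
    class = "group_result"
  )
}

#' Group-level sign-flipping permutation t-test
#'
#' Non-parametric one-sample test: the one-sample t statistic is recomputed
#' under random sign flips of the per-subject values and the p-value taken
#' from the rank of the observed statistic with the add-one estimator. The
#' attainable p is bounded below by the `2^-n` sign-flip resolution.
#'
#' @param values Per-subject values.
#' @param n_perm Number of sign-flip permutations (default 10000).
#' @param seed Optional integer seed.
#' @param tail `"greater"` or `"two.sided"`.
#' @param correction_k Bonferroni multiplier.
#' @return A `group_result`.
#' @export
group_permutation_t <- function(values, n_perm = 10000L, seed = NULL,
                                tail = c("greater", "two.sided"),
                                correction_k = 1) {
  tail <- match.arg(tail)
  n <- length(values)
  if (n < 2L) abort("need at least 2 values.")
  q <- sum(values^2)
  tfun <- function(m) {
    v <- (q - n * m^2) / (n - 1)
    ifelse(v <= 0, ifelse(m == 0, 0, Inf * sign(m)), m / sqrt(v / n))
  }
  t_obs <- tfun(mean(values))
  with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n, n_perm)
    m_perm <- colSums(signs * values) / n
    t_perm <- tfun(m_perm)
    stat_obs <- if (tail == "two.sided") abs(t_obs) else t_obs
    stat_perm <- if (tail == "two.sided") abs(t_perm) else t_perm
    p_raw <- (1 + sum(stat_perm >= stat_obs)) / (n_perm + 1)
    structure(
      list(statistic = t_obs, df = n - 1L, p = min(1, p_raw * correction_k),
           p_uncorrected = p_raw, tail = tail,
           correction = if (correction_k > 1) sprintf("bonferroni x%g", correction_k) else "none",
           mean = mean(values), sd = sd(values), n = n,
           cohens_d = mean(values) / sd(values),
           method = sprintf("sign-flip permutation (%d)", n_perm)),
      class = "group_result"
    )
  })
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf("<group_result> T_%d = %.3f, p = %.4g (%s, %s tail, %s)\n",
              x$df, x$statistic, x$p, x$method, x$tail, x$correction))
  invisible(x)
}
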