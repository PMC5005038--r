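# Subject-level permutation testing and group-level inference.

test_that("subject permutation p has add-one bounds and signed z", {
  ps <- simulate_trial_patterns(
    fix_trials, grid_model(orientation_deg = 3, amplitude_sd = 2,
                           baseline_sd = 0.2, noise_sd = 0.05),
    40, seed = 41)
  sim <- pairwise_similarity(ps)
  pr <- permutation_test_subject(sim, fix_labels, "mod60", n_perm = 200,
                                 seed = 42)
  # an observed contrast beyond every permutation hits the add-one floor
  expect_equal(pr$p, 1 / 201)
  expect_gt(pr$z, 0)
  expect_equal(pr$z, qnorm(1 - pr$p))
  expect_error(permutation_test_subject(sim, fix_labels, "mod60", n_perm = 50),
               "at least 100")
})

test_that("permutation test is reproducible and respects exclusions", {
  set.seed(43)
  sim <- pairwise_similarity(matrix(rnorm(96 * 20), 96, 20))
  a <- permutation_test_subject(sim, fix_labels, "mod60", n_perm = 150,
                                seed = 7)
  b <- permutation_test_subject(sim, fix_labels, "mod60", n_perm = 150,
                                seed = 7)
  expect_identical(a$p, b$p)
  ex <- permutation_test_subject(sim, fix_labels, "mod60",
                                 exclude = "same_block", n_perm = 150,
                                 seed = 7)
  expect_true(ex$p > 0 && ex$p <= 1)
})

test_that("degenerate single-direction labels are rejected", {
  trials <- fix_trials[1:5, ]
  trials$direction_deg <- 30
  labels <- label_pairs(trials, fix_layout)
  sim <- pairwise_similarity(matrix(rnorm(5 * 10), 5, 10))
  expect_error(permutation_test_subject(sim, labels, "mod60", n_perm = 100),
               "empty|degenerate")
})

test_that("null-data subject-level permutation p-values are uniform", {
  ps <- vapply(1:120, function(s) {
    trs <- generate_design(apply_exclusions(fix_combos, seed = s),
                           seed = 1000 + s)
    lbs <- label_pairs(trs, fix_layout)
    sim <- pairwise_similarity(
      simulate_trial_patterns(trs, null_model(), 30, seed = 2000 + s))
    permutation_test_subject(sim, lbs, "mod60", n_perm = 199,
                             seed = 3000 + s)$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("group one-sample t matches its closed form, df and error paths", {
  v <- c(0.1, 0.3, -0.2, 0.25, 0.05)
  g <- group_one_sample_t(v, tail = "two.sided")
  tt <- t.test(v)
  expect_equal(g$statistic, unname(tt$statistic))
  expect_equal(g$p, tt$p.value)
  expect_equal(g$df, 4L)
  # a 24-subject group tests with 23 degrees of freedom
  expect_equal(group_one_sample_t(rnorm(24))$df, 23L)
  # symmetric values give T = 0, two-tailed p = 1
  gs <- group_one_sample_t(c(-1, 1, -2, 2), tail = "two.sided")
  expect_equal(gs$statistic, 0)
  expect_equal(gs$p, 1)
  # Bonferroni doubles and caps the p
  g2 <- group_one_sample_t(v, tail = "two.sided", correction_k = 2)
  expect_equal(g2$p, min(1, 2 * tt$p.value))
  expect_error(group_one_sample_t(rep(0.5, 6)), "zero variance")
  expect_error(group_one_sample_t(0.5), "at least 2")
})

test_that("group permutation t matches exhaustive sign-flip enumeration for small n", {
  set.seed(44)
  v <- rnorm(10, mean = 0.4)
  # exhaustive oracle over all 2^10 sign flips
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 10)))
  tstat <- function(x) mean(x) / (sd(x) / sqrt(length(x)))
  t_all <- apply(signs, 1, function(s) tstat(s * v))
  p_exact <- mean(t_all >= tstat(v))
  g <- group_permutation_t(v, n_perm = 20000, seed = 45)
  expect_equal(g$p, p_exact, tolerance = 0.01)
  expect_equal(g$statistic, tstat(v))
  # all-zero values give p = 1
  expect_equal(group_permutation_t(rep(0, 8), n_perm = 500, seed = 1)$p, 1)
  # strongly positive values are bounded by the sign-flip resolution
  gpos <- group_permutation_t(rep(1, 10) + runif(10) / 10, n_perm = 5000,
                              seed = 2)
  expect_lt(gpos$p, 0.01)
  expect_gte(gpos$p, 1 / 5001)
})

test_that("parametric and permutation group tests agree in rank over cohorts", {
  set.seed(46)
  cohorts <- purrr::map(1:25, ~ rnorm(24, mean = runif(1, -0.2, 0.4)))
  pp <- purrr::map_dbl(cohorts, ~ group_one_sample_t(.x)$p)
  pn <- purrr::map_dbl(cohorts,
                       ~ group_permutation_t(.x, n_perm = 600, seed = 9)$p)
  expect_gt(cor(pp, pn, method = "spearman"), 0.95)
})

test_that("null cohorts reject at about the nominal rate", {
  set.seed(47)
  rej <- purrr::map_lgl(1:300, function(cc) {
    group_one_sample_t(rnorm(24), tail = "greater")$p < 0.05
  })
  # binomial 99% band around 0.05 with 300 draws
  expect_gt(mean(rej), 0.05 - 2.58 * sqrt(0.05 * 0.95 / 300))
  expect_lt(mean(rej), 0.05 + 2.58 * sqrt(0.05 * 0.95 / 300))
})

test_that("tidiers expose the result fields", {
  v <- rnorm(10, 0.2)
  g <- group_one_sample_t(v)
  expect_named(glance(g), c("statistic", "df", "p_value", "n"))
  expect_equal(tidy(g)$cohens_d, mean(v) / sd(v))
  ct <- condition_contrast(
    pairwise_similarity(matrix(rnorm(96 * 10), 96, 10)), fix_labels, "mod60")
  td <- tidy(ct)
  expect_equal(td$mean_z, c(ct$mean_a, ct$mean_b))
  expect_equal(glance(ct)$difference, ct$difference)
})
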