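# Pairwise similarity, condition contrasts, filters and distance
# residualization.

test_that("Fisher z matches the closed form and extremes are capped and flagged", {
  x <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 5), c(4, 3, 2, 1))
  sim <- pairwise_similarity(x)
  expect_equal(sim$z[sim$valid & abs(sim$r) < 1],
               atanh(sim$r[sim$valid & abs(sim$r) < 1]))
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)
  ident <- pairwise_similarity(rbind(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(ident$r, 1)
  expect_true(ident$capped)
  expect_true(is.finite(ident$z))
  # orthogonal mean-centered patterns
  orth <- pairwise_similarity(rbind(c(-1, 1, -1, 1), c(-1, -1, 1, 1)))
  expect_equal(orth$r, 0)
  expect_equal(orth$z, 0)
})

test_that("zero-variance patterns are flagged invalid and dropped from means", {
  x <- rbind(c(1, 1, 1), c(1, 2, 3), c(3, 2, 1))
  sim <- pairwise_similarity(x)
  expect_equal(sim$valid, c(FALSE, FALSE, TRUE))
  expect_true(all(is.na(sim$z[!sim$valid])))
})

test_that("pairwise similarity agrees with a brute-force oracle to 1e-12", {
  set.seed(12)
  for (rep in 1:3) {
    x <- matrix(rnorm(10 * 7), 10, 7)
    sim <- pairwise_similarity(x)
    orc <- oracle_pairwise_cor(x)
    expect_equal(sim$i, orc$i)
    expect_equal(sim$j, orc$j)
    expect_equal(sim$r, orc$r, tolerance = 1e-12)
  }
})

test_that("condition contrast reproduces a hand-enumerated example", {
  # 4 trials at 0, 60, 30, 90 degrees; z(0,60) = 0.5, z(30,90) = 0.3, rest 0.1
  trials <- tibble::tibble(
    trial_id = 1:4, block = 1L, start_id = 1L, target_id = 2L,
    direction_deg = c(0, 60, 30, 90), distance = 1,
    target_ring = "outer"
  )
  labels <- label_pairs(trials, fix_layout)
  z <- rep(0.1, 6)
  z[labels$i == 1 & labels$j == 2] <- 0.5
  z[labels$i == 3 & labels$j == 4] <- 0.3
  sim <- tibble::tibble(i = labels$i, j = labels$j, r = tanh(z), z = z,
                        valid = TRUE, capped = FALSE)
  ct <- condition_contrast(sim, labels, "mod60")
  expect_equal(ct$mean_a, 0.4)
  expect_equal(ct$mean_b, 0.1)
  expect_equal(ct$difference, 0.3)
})

test_that("equal z in all pairs gives zero contrast in every scheme", {
  sim <- tibble::tibble(i = fix_labels$i, j = fix_labels$j, r = 0.2,
                        z = atanh(0.2), valid = TRUE, capped = FALSE)
  for (scheme in c("onefold", "mod60", "mod90", "cardinal")) {
    expect_equal(condition_contrast(sim, fix_labels, scheme)$difference, 0)
  }
})

test_that("noiseless planted six-fold patterns reach the capped contrast extremes", {
  ps <- simulate_trial_patterns(
    fix_trials, grid_model(orientation_deg = 5, amplitude_sd = 1,
                           baseline_sd = 0, noise_sd = 0),
    40, seed = 1)
  sim <- pairwise_similarity(ps)
  # delta = 0 mod 60 -> identical patterns (r = 1); 30 mod 60 -> negated
  expect_true(all(sim$r[fix_labels$rem60 == 0] > 1 - 1e-12))
  expect_true(all(sim$r[fix_labels$rem60 == 30] < -1 + 1e-12))
  ct <- condition_contrast(sim, fix_labels, "mod60")
  expect_equal(ct$difference, 2 * atanh(1 - 1e-15), tolerance = 1e-6)
})

test_that("contrast is invariant to per-trial positive affine pattern rescaling", {
  set.seed(5)
  x <- matrix(rnorm(96 * 30), 96, 30)
  gains <- runif(96, 0.5, 2)
  shifts <- rnorm(96)
  y <- x * gains + shifts
  c1 <- condition_contrast(pairwise_similarity(x), fix_labels, "mod60")
  c2 <- condition_contrast(pairwise_similarity(y), fix_labels, "mod60")
  expect_equal(c1$difference, c2$difference, tolerance = 1e-12)
})

test_that("swapping condition labels negates the contrast", {
  set.seed(6)
  x <- matrix(rnorm(96 * 20), 96, 20)
  sim <- pairwise_similarity(x)
  ct <- condition_contrast(sim, fix_labels, "mod60")
  flipped <- fix_labels
  flipped$rem60 <- 30 - flipped$rem60
  expect_equal(condition_contrast(sim, flipped, "mod60")$difference,
               -ct$difference)
})

test_that("pair filters match brute-force counts and reject unknown names", {
  keep <- filter_pairs(fix_labels, "same_block")
  expect_equal(sum(!keep), 4L * choose(24, 2))
  expect_equal(sum(keep), 3456L)
  keep_inner <- filter_pairs(fix_labels, "both_inner_target")
  lost_a <- sum(fix_labels$rem60 == 0) - sum(fix_labels$rem60 == 0 & keep_inner)
  lost_b <- sum(fix_labels$rem60 == 30) - sum(fix_labels$rem60 == 30 & keep_inner)
  expect_equal(lost_a, 276L)
  expect_equal(lost_b, 0L)
  expect_equal(filter_pairs(fix_labels, character()), rep(TRUE, 4560L))
  expect_error(filter_pairs(fix_labels, "same_banana"), "unknown exclusion")
})

test_that("contrasts survive each documented exclusion filter with non-empty conditions", {
  set.seed(8)
  sim <- pairwise_similarity(matrix(rnorm(96 * 20), 96, 20))
  for (ex in c("same_start", "same_target", "same_combo", "same_block",
               "both_inner_target", "both_ns_street")) {
    ct <- condition_contrast(sim, fix_labels, "mod60", exclude = ex)
    expect_gt(ct$n_a, 0)
    expect_gt(ct$n_b, 0)
  }
})

test_that("distance residualization has the documented regression properties", {
  set.seed(7)
  sim <- pairwise_similarity(matrix(rnorm(96 * 25), 96, 25))
  # constant continuous predictor -> residuals are demeaned z, contrast unchanged
  lb_const <- fix_labels
  lb_const$dist_mean <- 5
  r1 <- residualize_distance(sim, lb_const, "mean")
  expect_equal(r1$z, sim$z - mean(sim$z), tolerance = 1e-12)
  expect_equal(condition_contrast(r1, fix_labels, "mod60")$difference,
               condition_contrast(sim, fix_labels, "mod60")$difference,
               tolerance = 1e-12)
  # predictor equal to z -> all residuals zero
  lb_z <- fix_labels
  lb_z$dist_mean <- sim$z
  r2 <- residualize_distance(sim, lb_z, "mean")
  expect_equal(max(abs(r2$z)), 0, tolerance = 1e-12)
  expect_equal(condition_contrast(r2, fix_labels, "mod60")$difference, 0,
               tolerance = 1e-12)
  # predictor orthogonal to the condition indicator leaves the contrast
  # untouched (Frisch-Waugh)
  ind <- as.numeric(fix_labels$rem60 == 0)
  raw <- rnorm(4560)
  ortho <- resid(lm(raw ~ ind))
  lb_o <- fix_labels
  lb_o$dist_mean <- ortho
  r3 <- residualize_distance(sim, lb_o, "mean")
  ca <- condition_contrast(r3, fix_labels, "mod60")$difference
  cb <- condition_contrast(sim, fix_labels, "mod60")$difference
  expect_equal(ca, cb, tolerance = 1e-10)
  # binary variant on the real measures; constant predictor errors
  r4 <- residualize_distance(sim, fix_labels, "neighborhood", binary = TRUE)
  expect_equal(nrow(r4), 4560L)
  expect_error(residualize_distance(sim, lb_const, "mean", binary = TRUE),
               "constant")
})
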