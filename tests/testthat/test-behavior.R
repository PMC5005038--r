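# Behavioral statistics, chance testing, map test, accuracy correlations and
# the visual-similarity control.

test_that("angular error wraps and is symmetric", {
  expect_equal(angular_error(350, 10), 20)
  expect_equal(angular_error(90, 90), 0)
  expect_equal(angular_error(0, 180), 180)
  expect_equal(angular_error(10, 350), angular_error(350, 10))
  expect_equal(angular_error(350 + 360, 10), 20)
})

test_that("chance-performance test excludes uniform responders and keeps accurate ones", {
  set.seed(51)
  uniform_err <- runif(96, 0, 180)
  out <- chance_performance_test(uniform_err)
  expect_true(out$exclude)
  good <- chance_performance_test(rep(c(4, 5, 6, 7), 24))
  expect_false(good$exclude)
  at_chance <- chance_performance_test(rep(90, 96))
  expect_true(at_chance$exclude)
  expect_true(at_chance$degenerate)
  expect_error(chance_performance_test(c(1, 2, 3)), "at least 6")
})

test_that("a uniform responder's error distribution matches the closed form", {
  trials <- fix_trials[rep(1:96, 40), ]
  trials$trial_id <- seq_len(nrow(trials))
  b <- simulate_behavior(trials, kappa = 1, lapse = 1, seed = 52)
  expect_equal(mean(b$error_deg), 90, tolerance = 1.5)
  expect_equal(median(b$error_deg), 90, tolerance = 2.5)
  expect_gt(ks.test(b$error_deg / 180, "punif")$p.value, 0.01)
})

test_that("combined error contrast multiplies pair errors and is null under independence", {
  errors <- rep(10, 96)
  errors[1] <- 20
  ct <- combined_error_contrast(errors, fix_labels)
  expect_equal(ct$n_a + ct$n_b, 4560L)
  # pair values are products of the two errors: 95 pairs involve trial 1
  # (value 20 * 10 = 200), the rest 10 * 10 = 100
  with1 <- fix_labels$i == 1 | fix_labels$j == 1
  total <- ct$mean_a * ct$n_a + ct$mean_b * ct$n_b
  expect_equal(total, 200 * sum(with1) + 100 * sum(!with1))
  # all-zero errors give zero contrast
  z <- combined_error_contrast(rep(0, 96), fix_labels)
  expect_equal(z$difference, 0)
  # direction-independent errors: expected contrast 0 over seeds
  diffs <- vapply(1:200, function(s) {
    e <- withr::with_seed(s, runif(96, 0, 120))
    combined_error_contrast(e, fix_labels)$difference
  }, numeric(1))
  expect_lt(abs(mean(diffs)) / (sd(diffs) / sqrt(200)), 3)
  # missing responses drop pairs
  em <- rep(10, 96); em[5] <- NA
  ctm <- suppressMessages(combined_error_contrast(em, fix_labels))
  expect_equal(ctm$n_a + ctm$n_b, 4560L - 95L)
})

test_that("map test scores Euclidean distances and z-scored accuracies standardize", {
  expect_equal(map_test_score(cbind(0, 0), cbind(3, 4)), 5)
  expect_equal(map_test_score(cbind(1, 1), cbind(1, 1)), 0)
  scores <- c(2, 4, 6, 8)
  zs <- as.vector(scale(scores))
  expect_equal(mean(zs), 0)
  expect_equal(sd(zs), 1)
})

test_that("accuracy correlations recover a shared latent factor across subjects", {
  set.seed(53)
  n <- 24
  latent <- rnorm(n)
  subjects <- tibble::tibble(
    mean_error_deg = 90 - 25 * latent + rnorm(n, 0, 5),
    buildings_found = round(30 + 6 * latent + rnorm(n, 0, 2)),
    training_error_deg = 60 - 15 * latent + rnorm(n, 0, 4),
    map_error = 50 - 10 * latent + rnorm(n, 0, 3) * -1,
    training_time = runif(n, 60, 120)
  )
  subjects$map_error <- 50 - 10 * latent + rnorm(n, 0, 3)
  out <- accuracy_correlations(subjects)
  expect_setequal(out$term, c("buildings_found", "training_accuracy", "map_test"))
  expect_true(all(out$r > 0.5))
  expect_true(all(out$p_value < 0.01))
  expect_true(all(!is.na(out$partial_r)))
  # perfect performer scores pi; chance performer about pi/2
  expect_equal(pi - 0 * pi / 180, pi)
  expect_equal(pi - 90 * pi / 180, pi / 2)
  bad <- subjects
  bad$buildings_found <- 10
  expect_error(accuracy_correlations(bad), "zero-variance")
})

test_that("image features behave under identity, inversion and translation", {
  views <- generate_views(fix_trials[1:6, ], fix_layout, width = 32L,
                          height = 24L)
  expect_length(views, 6L)
  expect_true(all(vapply(views, function(v) all(v >= 0 & v <= 1), logical(1))))
  # identical images correlate 1 on all defined dimensions
  sim_id <- image_feature_similarity(list(views[[1]], views[[1]]))
  expect_true(all(sim_id$r[sim_id$valid] > 1 - 1e-12))
  # luminance inversion flips the L correlation
  inv <- 1 - views[[1]]
  sim_inv <- image_feature_similarity(list(views[[1]], inv))
  expect_lt(sim_inv$r[sim_inv$dimension == "L" & sim_inv$valid], -0.99)
  # circular translation preserves FFT magnitude but not phase
  img <- views[[2]]
  shifted <- img[c(5:nrow(img), 1:4), , , drop = FALSE]
  sim_sh <- image_feature_similarity(list(img, shifted))
  r_mag <- sim_sh$r[sim_sh$dimension == "fft_magnitude"]
  r_phase <- sim_sh$r[sim_sh$dimension == "fft_phase"]
  expect_gt(r_mag, 1 - 1e-9)
  expect_lt(r_phase, r_mag)
  # constant channels are flagged undefined
  gray <- array(0.5, dim = dim(img))
  sim_g <- image_feature_similarity(list(gray, gray))
  expect_false(any(sim_g$valid[sim_g$dimension %in% c("a", "b")]))
  expect_error(image_feature_similarity(list(img, img[1:10, , ])), "dimensions")
})

test_that("visual similarity tests flag planted differences and not null ones", {
  set.seed(54)
  n <- 40
  trials <- fix_trials[1:n, ]
  labels <- label_pairs(trials, fix_layout)
  npair <- nrow(labels)
  base <- tidyr::expand_grid(k = seq_len(npair),
                             dimension = c("fft_magnitude", "fft_phase",
                                           "L", "a", "b"))
  feats <- tibble::tibble(
    i = labels$i[base$k], j = labels$j[base$k], dimension = base$dimension,
    r = 0, z = rnorm(nrow(base), 0, 0.05), valid = TRUE
  )
  out_null <- visual_similarity_tests(feats, labels)
  expect_false(any(out_null$significant))
  # plant lower phase similarity for similar-direction pairs
  similar <- labels$delta_deg <= 30 & !labels$same_start
  planted <- feats
  sel <- planted$dimension == "fft_phase" & similar[match(
    paste(planted$i, planted$j), paste(labels$i, labels$j))]
  planted$z[sel] <- planted$z[sel] - 0.2
  out <- visual_similarity_tests(planted, labels)
  row <- dplyr::filter(out, dimension == "fft_phase")
  expect_true(row$significant)
  expect_true(row$lower_for_similar)
  expect_false(any(out$significant[out$dimension != "fft_phase"]))
})
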