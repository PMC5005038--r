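# Planted-signal generators, behavioral simulation, embedding and cohorts.

test_that("noiseless grid patterns are identical at 0 mod 60 and negated at 30 mod 60", {
  trials <- fix_trials[1:12, ]
  ps <- simulate_trial_patterns(
    trials, grid_model(orientation_deg = 17, amplitude_sd = 1,
                       baseline_sd = 0, noise_sd = 0), 10, seed = 4)
  x <- ps$data
  for (i in 1:11) {
    for (j in (i + 1):12) {
      d <- delta_deg(trials$direction_deg[i], trials$direction_deg[j])
      if (d %% 60 == 0) {
        expect_equal(x[i, ], x[j, ], tolerance = 1e-12)
      } else {
        expect_equal(x[i, ], -x[j, ], tolerance = 1e-12)
      }
    }
  }
})

test_that("null model gives zero expected mod-60 contrast over seeds", {
  diffs <- vapply(1:40, function(s) {
    ps <- simulate_trial_patterns(fix_trials, null_model(), 40, seed = s)
    condition_contrast(pairwise_similarity(ps), fix_labels, "mod60")$difference
  }, numeric(1))
  expect_lt(abs(mean(diffs)) / (sd(diffs) / sqrt(length(diffs))), 3)
})

test_that("mean contrast is non-decreasing in grid amplitude over 50 seeds", {
  amps <- c(0.1, 0.3, 0.9)
  means <- vapply(amps, function(a) {
    mean(vapply(1:50, function(s) {
      ps <- simulate_trial_patterns(fix_trials, grid_model(amplitude_sd = a),
                                    40, seed = s)
      condition_contrast(pairwise_similarity(ps), fix_labels, "mod60")$difference
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("a planted six-fold signal drives mod-60 above mod-90 on average", {
  diffs <- vapply(1:30, function(s) {
    ps <- simulate_trial_patterns(fix_trials, grid_model(amplitude_sd = 0.6),
                                  60, seed = s)
    sim <- pairwise_similarity(ps)
    condition_contrast(sim, fix_labels, "mod60")$difference -
      condition_contrast(sim, fix_labels, "mod90")$difference
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs) / (sd(diffs) / sqrt(length(diffs))), 2)
})

test_that("pattern generation is bit-reproducible given a seed and errors on tiny regions", {
  a <- simulate_trial_patterns(fix_trials, grid_model(), 10, seed = 9)
  b <- simulate_trial_patterns(fix_trials, grid_model(), 10, seed = 9)
  expect_identical(a$data, b$data)
  expect_error(simulate_trial_patterns(fix_trials, grid_model(), 1),
               "n_voxels")
})

test_that("mixture models draw voxel populations in the given proportions", {
  m <- mixture_model(list(grid_model(noise_sd = 0), null_model(noise_sd = 0)),
                     c(0.5, 0.5))
  ps <- simulate_trial_patterns(fix_trials, m, 50, seed = 2)
  expect_equal(dim(ps$data), c(96L, 50L))
  expect_error(mixture_model(list(grid_model()), c(0.5, 0.5)), "weights")
})

test_that("behavioral simulation hits the documented accuracy regimes", {
  many <- fix_trials[rep(1:96, 30), ]
  many$trial_id <- seq_len(nrow(many))
  # lapse = 1: uniform responder, median absolute error near 90 degrees
  b1 <- simulate_behavior(many, kappa = 5, lapse = 1, seed = 3)
  expect_equal(median(b1$error_deg), 90, tolerance = 0.05)
  # kappa -> large, no lapses: all errors near 0
  b2 <- simulate_behavior(fix_trials, kappa = 1e6, lapse = 0, seed = 3)
  expect_lt(max(b2$error_deg), 1)
  # calibrated kappa reproduces the trained-cohort mean-error regime
  kap <- calibrate_kappa(33.68, lapse = 0)
  b3 <- simulate_behavior(many, kappa = kap, lapse = 0, seed = 4)
  expect_equal(mean(b3$error_deg), 33.68, tolerance = 1.5)
  expect_true(all(b3$error_deg >= 0 & b3$error_deg <= 180))
})

test_that("embedding round-trips planted patterns up to a positive affine transform", {
  tb <- dplyr::filter(fix_trials, block == 1)
  geom <- volume_geometry(shape = c(10L, 10L, 6L))
  nvox <- sum(geom$masks$pmEC_left)
  pat <- simulate_trial_patterns(tb, grid_model(amplitude_sd = 1), nvox,
                                 seed = 5)
  acq <- acquisition_params(drift_amplitude = 0, ar_coef = 0, noise_sd = 0,
                            motion_sd = 0, motion_loading_sd = 0)
  run <- embed_timeseries(pat, tb, geom, acq, mask = "pmEC_left", seed = 6)
  expect_equal(run$tr, 1.8)
  expect_equal(ncol(run$motion), 6L)
  ts <- ts_matrix(run$data, geom$masks$pmEC_left)
  rec <- extract_trial_patterns(ts, tb, tr = run$tr)
  # recovered patterns correlate ~1 with the planted ones trial by trial
  cors <- vapply(seq_len(nrow(tb)), function(k) {
    cor(rec$data[k, ], pat$data[k, ])
  }, numeric(1))
  expect_true(all(cors > 0.99))
})

test_that("nuisance residualization removes planted motion confounds", {
  tb <- dplyr::filter(fix_trials, block == 1)
  geom <- volume_geometry(shape = c(10L, 10L, 6L))
  nvox <- sum(geom$masks$pmEC_left)
  pat <- trial_pattern_set(matrix(0, nrow(tb), nvox), tb)
  acq <- acquisition_params(drift_amplitude = 0, ar_coef = 0, noise_sd = 0,
                            motion_sd = 0.2, motion_loading_sd = 1)
  run <- embed_timeseries(pat, tb, geom, acq, mask = "pmEC_left", seed = 7)
  ts <- ts_matrix(run$data, geom$masks$pmEC_left)
  res <- residualize_nuisance(ts, nuisance_model(run$motion))
  # residuals orthogonal to every motion column
  for (cc in 1:6) {
    expect_lt(max(abs(cor(res, run$motion[[cc]])), na.rm = TRUE), 1e-8)
  }
})

test_that("cohorts give each subject an independent design and reproducible draws", {
  spec <- cohort_spec(n_subjects = 3L, models = list(roi = null_model()),
                      n_voxels = 10L, seed = 11)
  co <- simulate_cohort(spec)
  expect_length(co$subjects, 3L)
  designs <- purrr::map(co$subjects, function(s) {
    paste(s$trials$start_id, s$trials$target_id, collapse = ",")
  })
  expect_gt(length(unique(unlist(designs))), 1L)
  for (s in co$subjects) expect_true(validate_design(s$trials))
  co2 <- simulate_cohort(cohort_spec(n_subjects = 3L,
                                     models = list(roi = null_model()),
                                     n_voxels = 10L, seed = 11))
  expect_identical(co$subjects[[2]]$patterns$roi$data,
                   co2$subjects[[2]]$patterns$roi$data)
  # empty cohort is fine; duplicate explicit seeds are not
  expect_length(simulate_cohort(cohort_spec(n_subjects = 0L, seed = 1))$subjects, 0L)
  expect_error(cohort_spec(n_subjects = 2L, subject_seeds = c(5L, 5L)),
               "duplicate")
})
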