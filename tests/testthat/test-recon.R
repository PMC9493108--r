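test_that("FSC behaves as a normalized shell correlation", {
  set.seed(16)
  m <- density_map(array(rnorm(16^3), dim = c(16, 16, 16)), 1)
  self <- fsc(m, m)
  expect_equal(self$correlations,
               rep(1, length(self$correlations)), tolerance = 1e-9)
  anti <- fsc(m, density_map(-m$data, 1))
  expect_equal(anti$correlations,
               rep(-1, length(anti$correlations)), tolerance = 1e-9)
  ## independent noise decorrelates beyond the lowest shells
  n2 <- density_map(array(rnorm(16^3), dim = c(16, 16, 16)), 1)
  ind <- fsc(m, n2)
  expect_lt(mean(abs(ind$correlations[-(1:2)])), 0.25)
  expect_error(fsc(m, density_map(array(0, c(8, 8, 8)), 1)),
               "identical")
})

test_that("FSC threshold crossing interpolates to a resolution in Angstrom", {
  curve <- structure(list(shell_freqs = (0:8) / 32,
                          correlations = c(1, 1, 0.9, 0.8, 0.6, 0.4,
                                           0.2, 0.1, 0.05),
                          n = 64, voxel_size = 0.5),
                     class = "fsc_curve")
  ## crosses 0.5 between shells 4 (0.6) and 5 (0.4) -> f = 0.140625
  expect_equal(fsc_resolution(curve, 0.5),
               1 / ((4 + 0.5) / 32), tolerance = 1e-12)
  ## never crossing returns Nyquist
  curve$correlations <- rep(1, 9)
  expect_equal(fsc_resolution(curve, 0.143), 1)
})

test_that("direct Fourier reconstruction recovers a known map from posed projections", {
  model <- helix_model()
  L <- 32L
  set.seed(17)
  K <- 400L
  euler <- random_euler(K)
  shift <- matrix(runif(2 * K, -3, 3), K, 2)
  imgs <- array(0, c(L, L, K))
  for (k in seq_len(K))
    imgs[, , k] <- project(model,
                           euler_to_rotation(euler[k, 1], euler[k, 2],
                                             euler[k, 3]),
                           shift[k, ], L, 1.5)
  rec <- particle_records(matrix(0, K, 1), euler, shift)
  vol <- reconstruct(imgs, rec, pixel_size = 1.5)
  truth <- render_density(model, L, 1.5)
  fc <- fsc(vol, truth)
  ## strong agreement through most of the band
  expect_true(all(fc$correlations[2:12] > 0.9))
  ## linearity: the average of two half-set reconstructions matches
  ## the full reconstruction up to gridding-weight differences
  h1 <- seq_len(K / 2)
  v1 <- reconstruct(imgs[, , h1], rec[h1, ], pixel_size = 1.5)
  v2 <- reconstruct(imgs[, , -h1], rec[-h1, ], pixel_size = 1.5)
  fc_halves <- fsc(density_map((v1$data + v2$data) / 2, 1.5), vol)
  expect_true(all(fc_halves$correlations[2:10] > 0.95))
  expect_error(reconstruct(array(0, c(8, 8, 0)), rec[0, ]), "empty")
})

test_that("identical-pose reconstruction degrades exactly as a missing-cone artifact", {
  model <- helix_model()
  L <- 32L
  K <- 60L
  euler <- matrix(rep(c(40, 70, 10), each = K), K, 3)
  imgs <- array(0, c(L, L, K))
  for (k in seq_len(K))
    imgs[, , k] <- project(model, euler_to_rotation(40, 70, 10),
                           c(0, 0), L, 1.5)
  rec <- particle_records(matrix(0, K, 1), euler, matrix(0, K, 2))
  vol <- reconstruct(imgs, rec, pixel_size = 1.5)
  fc <- fsc(vol, render_density(model, L, 1.5))
  ## informative only at the lowest shells; no error raised
  expect_gt(fc$correlations[2], 0.5)
  expect_lt(mean(fc$correlations[8:16]), 0.5)
})

test_that("doubling the image count never lowers the mean FSC on a noiseless fixture", {
  model <- helix_model()
  L <- 32L
  set.seed(18)
  K <- 240L
  euler <- random_euler(K)
  imgs <- array(0, c(L, L, K))
  for (k in seq_len(K))
    imgs[, , k] <- project(model,
                           euler_to_rotation(euler[k, 1], euler[k, 2],
                                             euler[k, 3]),
                           c(0, 0), L, 1.5)
  rec <- particle_records(matrix(0, K, 1), euler, matrix(0, K, 2))
  truth <- render_density(model, L, 1.5)
  f_half <- mean(fsc(reconstruct(imgs[, , 1:120], rec[1:120, ],
                                 pixel_size = 1.5),
                     truth)$correlations[2:12])
  f_full <- mean(fsc(reconstruct(imgs, rec, pixel_size = 1.5),
                     truth)$correlations[2:12])
  expect_gte(f_full + 0.01, f_half)
})

test_that("shift conventions are consistent across the downscale factor", {
  ## reconstructing original-size images with downscaled shifts x2
  ## equals reconstructing with natively recorded shifts
  model <- helix_model()
  L <- 32L
  set.seed(19)
  K <- 50L
  euler <- random_euler(K)
  shift <- matrix(runif(2 * K, -2, 2), K, 2)
  imgs <- array(0, c(L, L, K))
  for (k in seq_len(K))
    imgs[, , k] <- project(model,
                           euler_to_rotation(euler[k, 1], euler[k, 2],
                                             euler[k, 3]),
                           shift[k, ], L, 1.5)
  native <- particle_records(matrix(0, K, 1), euler, shift)
  downscaled <- particle_records(matrix(0, K, 1), euler, shift / 2)
  restored <- downscaled
  restored$sx <- restored$sx * 2
  restored$sy <- restored$sy * 2
  v1 <- reconstruct(imgs, native, pixel_size = 1.5)
  v2 <- reconstruct(imgs, restored, pixel_size = 1.5)
  expect_equal(v1$data, v2$data, tolerance = 1e-10)
})

test_that("evaluation metrics are exact on constructed errors", {
  model <- helix_model()
  modes <- helix_modes(3)
  n <- nrow(model$coords)
  set.seed(20)
  k <- 6L
  amp <- matrix(runif(3 * k, -100, 100), k, 3)
  euler <- random_euler(k)
  shift <- matrix(runif(2 * k, -3, 3), k, 2)
  truth <- particle_records(amp, euler, shift)
  ## identical records: every metric is zero
  ev0 <- evaluate_predictions(truth, truth, model, modes,
                              pixel_size = 2)
  expect_equal(ev0$amplitude_mae$over_modes[["mean"]], 0)
  expect_equal(ev0$angular[["mean"]], 0)
  expect_equal(ev0$rmsd$amplitudes[["mean"]], 0)
  ## single-mode amplitude error dq -> amplitude RMSD = |dq|/sqrt(N)
  pred <- truth
  pred$amp_1 <- pred$amp_1 + 12
  ev1 <- evaluate_predictions(pred, truth, model, modes)
  expect_equal(ev1$rmsd$amplitudes[["mean"]], 12 / sqrt(n),
               tolerance = 1e-10)
  expect_equal(ev1$amplitude_mae$over_modes[["mean"]], 4,
               tolerance = 1e-10)   # 12 on one of three modes
  ## pure shift error (delta, 0) -> shift RMSD = delta * pixel_size
  pred2 <- truth
  pred2$sx <- pred2$sx + 1.5
  ev2 <- evaluate_predictions(pred2, truth, model, modes,
                              pixel_size = 2)
  expect_equal(ev2$rmsd$shifts[["mean"]], 1.5 * 2, tolerance = 1e-10)
  expect_equal(ev2$shift_mae_A$x[["mean"]], 3, tolerance = 1e-10)
  ## RMSD metrics are symmetric in the two record sets
  ev_ab <- evaluate_predictions(pred, truth, model, modes)
  ev_ba <- evaluate_predictions(truth, pred, model, modes)
  expect_equal(ev_ab$rmsd$amplitudes, ev_ba$rmsd$amplitudes)
  expect_equal(ev_ab$rmsd$angles, ev_ba$rmsd$angles)
  expect_error(evaluate_predictions(truth[1:3, ], truth, model,
                                    modes), "length")
})
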