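test_that("Mahalanobis filtering removes far outliers and keeps the bulk", {
  set.seed(21)
  amp <- matrix(rnorm(300 * 3), 300, 3)
  amp[1, ] <- c(10, 10, 10)
  rec <- particle_records(amp, random_euler(300),
                          matrix(0, 300, 2), provenance = "hemnma")
  kept <- mahalanobis_filter(rec, threshold = 3.2)
  expect_equal(attr(kept, "removed") >= 1, TRUE)
  expect_false(10 %in% kept$amp_1)
  ## an infinite threshold keeps everything
  all_kept <- mahalanobis_filter(rec, threshold = 1e9)
  expect_equal(nrow(all_kept), 300L)
  ## singular covariance reports the ridge escape hatch
  degen <- particle_records(cbind(amp[, 1], amp[, 1], amp[, 1]),
                            random_euler(300), matrix(0, 300, 2))
  expect_error(mahalanobis_filter(degen, 3.2), "ridge")
  expect_equal(nrow(mahalanobis_filter(degen, 3.2, ridge = 1e-6)) > 0,
               TRUE)
})

test_that("PCA spaces reproduce degenerate and analytic variance structure", {
  set.seed(22)
  ## a perfect line: PC1 explains everything
  t <- runif(200)
  line <- cbind(2 * t, -t, 0.5 * t)
  sp <- pca_fit(line, d = 2)
  expect_gt(sp$explained_variance[1] /
              sum(apply(line, 2, stats::var)), 0.999)
  expect_true(all(diff(sp$explained_variance) <= 1e-12))
  ## analytic helix: d=2 residual equals the known out-of-plane
  ## variance (smallest eigenvalue of the helix covariance)
  r <- runif(4000)
  helix <- cbind(-200 * r, 200 * sin(pi * r), 200 * cos(pi * r))
  sp2 <- pca_fit(helix, d = 2)
  ev <- eigen(stats::cov(helix), symmetric = TRUE)$values
  resid <- helix - pca_backproject(sp2, sp2$embedding)
  expect_equal(mean(rowSums(resid^2)) * 4000 / 3999 / 1, ev[3],
               tolerance = 0.02 * ev[3])
  ## explained variances bounded by the total
  expect_lte(sum(sp2$explained_variance),
             sum(apply(helix, 2, stats::var)) + 1e-9)
  expect_error(pca_fit(helix, d = 5), "exceeds")
  ## deterministic sign convention: largest loading positive
  for (j in 1:2) {
    l <- sp2$components[j, ]
    expect_gt(l[which.max(abs(l))], 0)
  }
})

test_that("nearby embedding points have nearby latent coordinates", {
  set.seed(23)
  r <- runif(1500)
  helix <- cbind(-200 * r, 200 * sin(pi * r), 200 * cos(pi * r))
  sp <- pca_fit(helix, d = 2)
  ## rank correlation between PC-space distance to a probe point and
  ## |delta r| is positive in its neighborhood
  probe <- 17L
  d_emb <- sqrt(rowSums(sweep(sp$embedding, 2,
                              sp$embedding[probe, ])^2))
  nb <- order(d_emb)[2:151]
  ct <- stats::cor(d_emb[nb], abs(r[nb] - r[probe]),
                   method = "spearman")
  expect_gt(ct, 0.3)
})

test_that("group selection covers boxes and quasi-uniform PC1 bins", {
  set.seed(24)
  r <- runif(2000)
  amp <- cbind(-200 * r, 200 * sin(pi * r), 200 * cos(pi * r)) +
    matrix(rnorm(6000, 0, 5), ncol = 3)
  sp <- pca_fit(amp, d = 2)
  ## one box covering everything -> a single total group
  lim <- apply(sp$embedding, 2, range)
  all_box <- select_groups(sp, regions = list(lim))
  expect_equal(length(all_box$groups), 1L)
  expect_equal(length(all_box$groups[[1]]), 2000L)
  ## disjoint boxes give disjoint assignments
  mid <- stats::median(sp$embedding[, 1])
  b1 <- rbind(c(lim[1, 1], lim[1, 2]), c(mid, lim[2, 2]))
  b2 <- rbind(c(mid + 1e-9, lim[1, 2]), c(lim[2, 1], lim[2, 2]))
  two <- select_groups(sp, regions = list(b1, b2))
  expect_length(intersect(two$groups[[1]], two$groups[[2]]), 0)
  ## PC1 bins: equal-count split with tails discarded, all bins at
  ## least the minimum size
  bins <- select_groups(sp, pc1_bins = 7, tail_fraction = 0.05,
                        min_group_size = 100)
  expect_equal(length(bins$groups), 7L)
  expect_true(all(lengths(bins$groups) >= 100))
  expect_lt(diff(range(lengths(bins$groups))), 10)
  ## undersized groups are dropped with a warning
  expect_warning(
    select_groups(sp, pc1_bins = 7, min_group_size = 1000),
    "min_group_size")
})

test_that("animation walks the embedding and degenerates correctly", {
  model <- helix_model()
  modes <- helix_modes(3)
  set.seed(25)
  r <- runif(300)
  amp <- cbind(-60 * r, 60 * sin(pi * r), 60 * cos(pi * r))
  rec <- particle_records(amp, random_euler(300), matrix(0, 300, 2))
  sp <- pca_fit(rec, d = 2)
  ## a single frame at score zero is the mean conformation
  f1 <- animate_space(sp, model, modes, n_frames = 1)
  mean_conf <- apply_amplitudes(model, modes, colMeans(amp))
  expect_equal(f1[[1]]$coords, mean_conf$coords, tolerance = 1e-8)
  ## frames move monotonically away from the first frame
  fr <- animate_space(sp, model, modes, n_frames = 6)
  rmsd0 <- vapply(fr, function(f)
    sqrt(mean(rowSums((f$coords - fr[[1]]$coords)^2))), numeric(1))
  expect_true(all(diff(rmsd0) > 0))
  ## zero-variance amplitudes give identical frames
  rec0 <- particle_records(matrix(5, 50, 3), random_euler(50),
                           matrix(0, 50, 2))
  sp0 <- pca_fit(rec0, d = 1)
  fr0 <- animate_space(sp0, model, modes, n_frames = 3)
  expect_equal(fr0[[1]]$coords, fr0[[3]]$coords, tolerance = 1e-8)
  ## multi-model PDB output is written
  f <- tempfile(fileext = ".pdb")
  animate_space(sp, model, modes, n_frames = 3, path = f)
  expect_equal(sum(grepl("^MODEL", readLines(f))), 3L)
})

test_that("merging spaces preserves provenance and PCA directions", {
  set.seed(26)
  amp <- matrix(rnorm(600), 200, 3)
  a <- particle_records(amp, random_euler(200), matrix(0, 200, 2),
                        provenance = "inferred")
  b <- particle_records(amp, random_euler(200), matrix(0, 200, 2),
                        provenance = "hemnma")
  merged <- merge_spaces(a, b)
  expect_equal(nrow(merged$embedding), 400L)
  expect_equal(sum(merged$provenance == "inferred"), 200L)
  ## duplicating a set leaves the principal directions unchanged
  solo <- pca_fit(a, d = 2)
  dup <- merge_spaces(a, a)
  for (j in 1:2)
    expect_equal(abs(sum(dup$components[j, ] * solo$components[j, ])),
                 1, tolerance = 1e-8)
  ## dimension mismatch is an error
  b2 <- particle_records(matrix(0, 5, 2), random_euler(5),
                         matrix(0, 5, 2))
  expect_error(merge_spaces(a, b2), "dimensions")
})
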