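test_that("the two-body ENM has the analytic spectrum {2, 0 x 5}", {
  m <- coarse_model(rbind(c(0, 0, 0), c(1, 0, 0)))
  h <- build_enm_hessian(m, 2)
  ev <- sort(eigen(h, symmetric = TRUE)$values)
  expect_equal(ev, c(0, 0, 0, 0, 0, 2), tolerance = 1e-12)
  ## rows sum to zero (translation invariance)
  expect_lt(max(abs(rowSums(h))), 1e-12)
  ## no springs below the minimum distance -> zero matrix
  expect_equal(build_enm_hessian(m, 0.5),
               matrix(0, 6, 6))
  ## coincident points are rejected
  expect_error(build_enm_hessian(
    coarse_model(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1))), 2),
    "coincide")
})

test_that("a connected model has exactly 6 rigid-body modes and orthonormal flexibles", {
  h <- build_enm_hessian(helix_model(), 8)
  ev <- sort(eigen(h, symmetric = TRUE)$values)
  expect_equal(sum(abs(ev) < 1e-8 * ev[7]), 6L)
  ms <- helix_modes(5)
  gram <- crossprod(ms$vectors)
  expect_lt(max(abs(gram - diag(5))), 1e-6)
  expect_true(all(diff(ms$eigenvalues) >= -1e-12))
  expect_error(compute_modes(h, 3 * 48 - 5), "available")
})

test_that("two connected components double the rigid-body subspace", {
  a <- helix_model()$coords
  b <- sweep(a, 2, c(100, 0, 0), "+")   # far beyond the radius
  m <- coarse_model(rbind(a, b))
  h <- build_enm_hessian(m, 8)
  ev <- sort(eigen(h, symmetric = TRUE)$values)
  expect_equal(sum(abs(ev) < 1e-8 * ev[13]), 12L)
})

test_that("small-model eigenpairs match a dense brute-force diagonalization", {
  set.seed(8)
  m <- make_helix_model(n = 16, seed = 8)
  h <- build_enm_hessian(m, 8)
  ms <- compute_modes(h, 4, interaction_radius = 8)
  ## independent oracle: base eigen on the same symmetric matrix with
  ## explicit ascending ordering
  e <- eigen(h, symmetric = TRUE)
  vals <- rev(e$values)
  vecs <- e$vectors[, rev(seq_len(ncol(e$vectors)))]
  expect_equal(ms$eigenvalues, vals[7:10], tolerance = 1e-8)
  for (k in 1:4) {
    ## compare up to sign
    dot <- abs(sum(ms$vectors[, k] * vecs[, 6 + k]))
    expect_equal(dot, 1, tolerance = 1e-6)
  }
})

test_that("RTB modes reproduce and bound the full ENM", {
  m <- helix_model()
  h <- build_enm_hessian(m, 8)
  full <- helix_modes(3)
  ## block_size 1: every residue its own rigid block; low modes agree
  ## with full ENM within a small subspace angle
  rtb1 <- compute_modes_rtb(m, h, 1, 3)
  for (k in 1:3) {
    dot <- abs(sum(rtb1$vectors[, k] * full$vectors[, k]))
    expect_gt(dot, cos(5 * pi / 180))
  }
  ## Rayleigh-Ritz: projected eigenvalues never undercut the full ones
  rtb5 <- compute_modes_rtb(m, h, 5, 3)
  expect_true(all(rtb5$eigenvalues >= full$eigenvalues - 1e-10))
  ## a single block leaves no flexible modes
  expect_error(compute_modes_rtb(m, h, 100, 1), "flexible")
  ## two-body analytic case: one point per block spans the full 6-dim
  ## configuration space, so the complete RTB spectrum (a linear pair
  ## has 5 rigid freedoms plus the 2-gamma stretch) matches the full
  ## ENM exactly
  m2 <- coarse_model(rbind(c(0, 0, 0), c(1, 0, 0)))
  h2 <- build_enm_hessian(m2, 2)
  r2 <- compute_modes_rtb(m2, h2, 1, 6, skip_rigid = FALSE,
                          interaction_radius = 2)
  f2 <- compute_modes(h2, 6, skip_rigid = FALSE,
                      interaction_radius = 2)
  expect_equal(r2$eigenvalues, f2$eigenvalues, tolerance = 1e-10)
  expect_equal(max(r2$eigenvalues), 2, tolerance = 1e-10)
})

test_that("amplitude displacement obeys the unit-norm mode algebra", {
  m <- helix_model()
  ms <- helix_modes(3)
  n <- nrow(m$coords)
  ## zero amplitudes: identity
  expect_equal(apply_amplitudes(m, ms, c(0, 0, 0))$coords, m$coords)
  ## single-mode displacement norm equals |q|; RMSD = |q|/sqrt(N)
  q <- 7.3
  d <- apply_amplitudes(m, ms, c(q, 0, 0))$coords - m$coords
  expect_equal(sqrt(sum(d^2)), abs(q), tolerance = 1e-10)
  expect_equal(sqrt(mean(rowSums(d^2))), abs(q) / sqrt(n),
               tolerance = 1e-10)
  ## applying -q undoes q
  back <- apply_amplitudes(apply_amplitudes(m, ms, c(3, -4, 5)), ms,
                           -c(3, -4, 5))
  expect_equal(back$coords, m$coords, tolerance = 1e-10)
  expect_error(apply_amplitudes(m, ms, c(1, 2)), "amplitudes")
})

test_that("pseudoatomization recovers a known point model from its map", {
  set.seed(9)
  pts <- rbind(c(-6, 0, 0), c(6, 0, 0), c(0, 6, 0), c(0, -6, 2),
               c(0, 0, -6))
  truth <- coarse_model(pts, gaussian_sigma = 1.2)
  map <- render_density(truth, 24, 1.0)
  ps <- pseudoatomize(map, 5, threshold = 1e-4)
  ## every true center recovered within one voxel
  for (i in 1:5) {
    d <- sqrt(min(rowSums(sweep(ps$coords, 2, pts[i, ])^2)))
    expect_lt(d, 1.0)
  }
  expect_gt(attr(ps, "map_correlation"), 0.9)
  ## more pseudoatoms never fit an extended density worse
  ext <- helix_model()
  ext$gaussian_sigma <- 1.5          # matches the pseudoatom width
  ext_map <- render_density(ext, 24, 1.0)
  corrs <- vapply(c(5L, 10L, 20L), function(k)
    attr(pseudoatomize(ext_map, k, threshold = 1e-4),
         "map_correlation"), numeric(1))
  expect_true(all(diff(corrs) > -1e-6))
  expect_error(pseudoatomize(map, 5, threshold = max(map$data) + 1),
               "empty")
  expect_error(pseudoatomize(map, 1e7, threshold = 1e-4), "exceeds")
})

test_that("mode sets round-trip through the plain-text layout", {
  ms <- helix_modes(3)
  d <- tempfile()
  write_modes(d, ms)
  ms2 <- read_modes(d)
  expect_equal(ms2$eigenvalues, ms$eigenvalues, tolerance = 1e-12)
  expect_equal(ms2$vectors, unname(ms$vectors), tolerance = 1e-10)
})
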