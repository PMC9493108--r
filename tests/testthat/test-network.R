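test_that("model heads are sized by the target type", {
  expect_equal(network_config("quaternion")$output_dim, 4L)
  expect_equal(network_config("shifts")$output_dim, 2L)
  expect_equal(network_config("amplitudes", output_dim = 3L)$output_dim,
               3L)
  expect_error(network_config("amplitudes"), "output_dim")
  expect_error(network_config("quaternion", output_dim = 3),
               "must be 4")
  expect_error(network_config("shifts", depth = "77"), "depth")
  net_q <- build_model(network_config("quaternion", depth = "tiny"),
                       32L)
  net_s <- build_model(network_config("shifts", depth = "tiny"), 32L)
  x <- array(0, c(32, 32, 1, 2))
  yq <- nmaflex:::.forward_net(net_q, x)$y
  ys <- nmaflex:::.forward_net(net_s, x)$y
  expect_equal(dim(yq), c(4L, 2L))
  expect_equal(dim(ys), c(2L, 2L))
  ## forward pass on a zero image stays finite
  expect_true(all(is.finite(yq)))
})

test_that("the deeper residual variants assemble and run forward", {
  for (depth in c("18", "50")) {
    net <- build_model(network_config("shifts", depth = depth), 64L)
    y <- nmaflex:::.forward_net(net,
                                array(rnorm(64 * 64), c(64, 64, 1, 1)))$y
    expect_equal(dim(y), c(2L, 1L))
    expect_true(all(is.finite(y)))
  }
})

test_that("training reduces the loss on a separable toy and is deterministic", {
  set.seed(27)
  L <- 24L
  n <- 120L
  sh <- matrix(runif(2 * n, -3, 3), n, 2)
  imgs <- array(0, c(L, L, n))
  gx <- seq_len(L) - 1 - L / 2
  for (i in seq_len(n))
    imgs[, , i] <- exp(-outer((gx - sh[i, 1])^2,
                              (gx - sh[i, 2])^2, "+") / 6) +
      matrix(rnorm(L * L, 0, 0.05), L, L)
  cfg <- network_config("shifts", depth = "tiny", dropout = 0.2,
                        lr0 = 1e-3, lr_decay_every = 1000L,
                        epochs = 6L, batch_size = 16L, seed = 7L)
  net <- build_model(cfg, L)
  fit <- train_network(net, imgs[, , 1:96], sh[1:96, ],
                       imgs[, , 97:120], sh[97:120, ])
  expect_lt(tail(fit$training_log$train_mae, 1),
            fit$training_log$train_mae[1])
  ## validation error well inside the +/-3 px shift range
  expect_lt(min(fit$training_log$val_mae), 0.2 * 6)
  ## two runs with the same seed coincide exactly
  fit2 <- train_network(build_model(cfg, L), imgs[, , 1:96],
                        sh[1:96, ], imgs[, , 97:120], sh[97:120, ])
  expect_identical(fit$training_log, fit2$training_log)
  ## an empty validation set refuses to train
  expect_error(train_network(net, imgs[, , 1:96], sh[1:96, ],
                             imgs[, , integer(0)], sh[0, ]),
               "validation")
})

test_that("prediction inverts the scalers and canonicalizes quaternions", {
  set.seed(28)
  L <- 16L
  n <- 40L
  imgs <- array(rnorm(L * L * n), c(L, L, n))
  q <- t(sapply(seq_len(n), function(i) {
    e <- random_euler(1)
    euler_to_quaternion(e[1], e[2], e[3])
  }))
  cfg <- network_config("quaternion", depth = "tiny", dropout = 0,
                        lr0 = 1e-4, epochs = 2L, batch_size = 8L,
                        seed = 9L)
  fit <- train_network(build_model(cfg, L), imgs[, , 1:32], q[1:32, ],
                       imgs[, , 33:40], q[33:40, ])
  pr <- predict_network(fit, imgs[, , 33:40])
  qq <- attr(pr, "quaternion")
  expect_equal(sqrt(rowSums(qq^2)), rep(1, 8), tolerance = 1e-9)
  expect_true(all(qq[, 1] >= 0))
  ## batch inference equals per-image inference
  one <- predict_network(fit, imgs[, , 33, drop = FALSE])
  expect_equal(records_euler(one), records_euler(pr)[1, , drop = FALSE],
               tolerance = 1e-9, ignore_attr = TRUE)
  ## size mismatch is refused
  expect_error(predict_network(fit, array(0, c(32, 32, 1))), "size")
})

test_that("target standardization round-trips and ignores quaternions", {
  set.seed(29)
  lab <- matrix(rnorm(50 * 3, mean = 40, sd = 12), 50, 3)
  sc <- nmaflex:::.fit_scalers(lab, "amplitudes")
  back <- nmaflex:::.invert_scalers(nmaflex:::.apply_scalers(lab, sc),
                                    sc)
  expect_equal(back, lab, tolerance = 1e-12)
  scq <- nmaflex:::.fit_scalers(lab, "quaternion")
  expect_equal(scq$mean, rep(0, 3))
  expect_equal(scq$sd, rep(1, 3))
})

test_that("quaternion label sign is irrelevant after canonicalization", {
  set.seed(30)
  q <- t(sapply(1:10, function(i) {
    e <- random_euler(1)
    euler_to_quaternion(e[1], e[2], e[3])
  }))
  flipped <- q
  flipped[c(2, 5, 9), ] <- -flipped[c(2, 5, 9), ]
  expect_equal(nmaflex:::.canonicalize_rows(flipped),
               nmaflex:::.canonicalize_rows(q))
})

test_that("dataset splits are disjoint, reproducible and optionally stratified", {
  ## the reference 20,000 / 50,000 split of 70,000 expressed as
  ## fractions
  idx <- split_dataset(70000L, c(train = 2 / 7, large_test = 5 / 7),
                       seed = 5L)
  expect_equal(length(idx$train), 20000L)
  expect_equal(length(idx$large_test), 50000L)
  expect_length(intersect(idx$train, idx$large_test), 0)
  idx2 <- split_dataset(70000L, c(train = 2 / 7, large_test = 5 / 7),
                        seed = 5L)
  expect_identical(idx, idx2)
  ## subsets stay inside the index range and are pairwise disjoint
  all_idx <- unlist(idx)
  expect_true(all(all_idx >= 1 & all_idx <= 70000))
  expect_equal(anyDuplicated(all_idx), 0L)
  ## stratification balances classes in every subset
  strata <- rep(c("a", "b"), each = 500)
  s <- split_dataset(1000L, c(train = 0.5, test = 0.3), seed = 6L,
                     strata = strata)
  expect_equal(sum(strata[s$train] == "a"), 250L)
  expect_equal(sum(strata[s$test] == "b"), 150L)
  expect_error(split_dataset(10L, c(a = 0.9, b = 0.3)), "sum")
})

test_that("checkpoints round-trip through the text format", {
  set.seed(31)
  L <- 16L
  imgs <- array(rnorm(L * L * 12), c(L, L, 12))
  sh <- matrix(runif(24, -2, 2), 12, 2)
  cfg <- network_config("shifts", depth = "tiny", dropout = 0,
                        epochs = 1L, batch_size = 4L, seed = 3L)
  fit <- train_network(build_model(cfg, L), imgs[, , 1:8], sh[1:8, ],
                       imgs[, , 9:12], sh[9:12, ])
  f <- tempfile(fileext = ".ckpt")
  save_network(fit, f)
  fit2 <- load_network(f)
  p1 <- predict_network(fit, imgs[, , 9:12])
  p2 <- predict_network(fit2, imgs[, , 9:12])
  expect_equal(records_shift(p1), records_shift(p2),
               tolerance = 1e-12)
})
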