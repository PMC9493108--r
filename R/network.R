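## The deep regressor: a residual CNN feature extractor followed by a
## 4-layer MLP head (1000, 512, 128 hidden nodes, ReLU, dropout; linear
## output), trained with mean-absolute-error loss and Adam, separately
## per parameter type (normal-mode amplitudes, unit quaternions,
## in-plane shifts).
##
## The engine is self-contained: layers are R lists, convolutions run
## through im2col + GEMM kernels in C++, batch norm / activations /
## dense layers and the Adam update live in R.  Everything is
## deterministic given the config seed (single-threaded BLAS order is
## stable run to run).
##
## Activation layout: (H, W, C, B) column-major arrays; dense
## activations are (features, B) matrices.

# ---------------------------------------------------------------------
# Config

#' Network configuration
#'
#' Defaults follow the reference training protocol: ResNet-34 depth,
#' MLP widths 1000/512/128, dropout 0.5 on the MLP, MAE loss, Adam
#' with starting learning rate 1e-5 divided by 10 every 80 epochs,
#' weight decay 1e-5, batch size 2, 400 epochs.  The `"tiny"` depth is
#' an 8-layer variant that makes the full pipeline testable on one
#' CPU; depths 50/101 use bottleneck blocks.
#'
#' @param target_type `"amplitudes"`, `"quaternion"` or `"shifts"`.
#' @param output_dim Number of outputs: M for amplitudes (required),
#'   fixed 4 for quaternions, 2 for shifts.
#' @param depth `"tiny"`, `"18"`, `"34"`, `"50"` or `"101"`.
#' @param head_widths Hidden MLP widths.
#' @param dropout MLP dropout probability.
#' @param weight_decay L2 coefficient added to the gradients.
#' @param lr0 Starting learning rate.
#' @param lr_decay_every Epoch interval at which lr is divided by 10.
#' @param epochs,batch_size Training schedule.
#' @param seed RNG seed controlling init, shuffling and dropout.
#' @return An object of class `network_config`.
#' @export
network_config <- function(target_type = c("amplitudes", "quaternion",
                                           "shifts"),
                           output_dim = NULL, depth = "34",
                           head_widths = c(1000L, 512L, 128L),
                           dropout = 0.5, weight_decay = 1e-5,
                           lr0 = 1e-5, lr_decay_every = 80L,
                           epochs = 400L, batch_size = 2L,
                           seed = 1L) {
  target_type <- match.arg(target_type)
  fixed <- c(quaternion = 4L, shifts = 2L)
  if (target_type %in% names(fixed)) {
    if (!is.null(output_dim) && output_dim != fixed[[target_type]])
      stop(sprintf("output_dim for %s must be %d", target_type,
                   fixed[[target_type]]))
    output_dim <- fixed[[target_type]]
  } else if (is.null(output_dim))
    stop("output_dim (number of modes) is required for amplitudes")
  depth <- as.character(depth)
  if (!depth %in% c("tiny", "18", "34", "50", "101"))
    stop("unknown depth: ", depth)
  structure(list(target_type = target_type,
                 output_dim = as.integer(output_dim), depth = depth,
                 head_widths = as.integer(head_widths),
                 dropout = dropout, weight_decay = weight_decay,
                 lr0 = lr0, lr_decay_every = as.integer(lr_decay_every),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = seed),
            class = "network_config")
}

# ---------------------------------------------------------------------
# Layers

.he_conv <- function(k, cin, cout) {
  array(stats::rnorm(k * k * cin * cout,
                     sd = sqrt(2 / (k * k * cin))),
        dim = c(k, k, cin, cout))
}

.layer_conv <- function(k, cin, cout, stride = 1L, pad = (k - 1L) %/% 2L)
  list(type = "conv", w = .he_conv(k, cin, cout), b = numeric(cout),
       stride = as.integer(stride), pad = as.integer(pad))

.layer_bn <- function(c)
  list(type = "bn", gamma = rep(1, c), beta = numeric(c),
       rmean = numeric(c), rvar = rep(1, c), momentum = 0.1,
       eps = 1e-5)

.layer_relu <- function() list(type = "relu")

.layer_dense <- function(fin, fout, activation = "relu",
                         dropout = 0) {
  list(type = "dense",
       w = matrix(stats::rnorm(fout * fin, sd = sqrt(2 / fin)),
                  fout, fin),
       b = numeric(fout), activation = activation, dropout = dropout)
}

## ---- forward / backward for primitive layers -------------------------

.fwd_layer <- function(layer, x, training) {
  switch(layer$type,
    conv = {
      if (training) {
        r <- cpp_conv2d_forward_cache(x, layer$w, layer$b,
                                      layer$stride, layer$pad)
        list(y = r$y, cache = list(cols = r$cols, xdim = dim(x)))
      } else {
        y <- cpp_conv2d_forward(x, layer$w, layer$b, layer$stride,
                                layer$pad)
        list(y = y, cache = NULL)
      }
    },
    bn = {
      if (training) {
        st <- cpp_bn_stats(x)
        mu <- st$mu
        va <- st$va
      } else {
        mu <- layer$rmean
        va <- layer$rvar
      }
      y <- cpp_bn_forward(x, layer$gamma, layer$beta, mu, va,
                          layer$eps)
      list(y = y, cache = list(x = x, mu = mu, va = va,
                               training = training))
    },
    relu = {
      y <- cpp_relu_forward(x)
      list(y = y, cache = y)
    },
    stop("unknown layer type ", layer$type))
}

.bwd_layer <- function(layer, cache, dy) {
  switch(layer$type,
    conv = {
      g <- cpp_conv2d_backward_cached(cache$cols, layer$w, dy,
                                      cache$xdim, layer$stride,
                                      layer$pad)
      list(dx = g$dx, grads = list(w = g$dw, b = g$db))
    },
    bn = {
      g <- cpp_bn_backward(cache$x, dy, layer$gamma, cache$mu,
                           cache$va, layer$eps, cache$training)
      list(dx = g$dx, grads = list(gamma = g$dgamma,
                                   beta = g$dbeta))
    },
    relu = {
      list(dx = cpp_relu_backward(cache, dy), grads = NULL)
    })
}

## fold the batch statistics cached by a training forward pass into the
## BN running buffers (exponential moving average)
.update_bn_from_caches <- function(net, caches) {
  upd <- function(ly, cc) {
    if (ly$type == "bn" && !is.null(cc) && isTRUE(cc$training)) {
      ly$rmean <- (1 - ly$momentum) * ly$rmean + ly$momentum * cc$mu
      ly$rvar <- (1 - ly$momentum) * ly$rvar + ly$momentum * cc$va
    }
    ly
  }
  for (i in seq_along(net$stages)) {
    st <- net$stages[[i]]
    cc <- caches[[i]]
    if (st$kind == "plain") {
      for (j in seq_along(st$layers))
        net$stages[[i]]$layers[[j]] <- upd(st$layers[[j]], cc[[j]])
    } else if (st$kind == "res") {
      for (j in seq_along(st$main))
        net$stages[[i]]$main[[j]] <- upd(st$main[[j]], cc$main[[j]])
      if (!is.null(st$short))
        for (j in seq_along(st$short))
          net$stages[[i]]$short[[j]] <- upd(st$short[[j]],
                                            cc$short[[j]])
    }
  }
  net
}

# ---------------------------------------------------------------------
# Architecture

.basic_block <- function(cin, cout, stride) {
  list(kind = "res",
       main = list(.layer_conv(3L, cin, cout, stride), .layer_bn(cout),
                   .layer_relu(),
                   .layer_conv(3L, cout, cout, 1L), .layer_bn(cout)),
       short = if (stride != 1L || cin != cout)
         list(.layer_conv(1L, cin, cout, stride, pad = 0L),
              .layer_bn(cout)) else NULL)
}

.bottleneck_block <- function(cin, cmid, stride) {
  cout <- 4L * cmid
  list(kind = "res",
       main = list(.layer_conv(1L, cin, cmid, 1L, pad = 0L),
                   .layer_bn(cmid), .layer_relu(),
                   .layer_conv(3L, cmid, cmid, stride), .layer_bn(cmid),
                   .layer_relu(),
                   .layer_conv(1L, cmid, cout, 1L, pad = 0L),
                   .layer_bn(cout)),
       short = if (stride != 1L || cin != cout)
         list(.layer_conv(1L, cin, cout, stride, pad = 0L),
              .layer_bn(cout)) else NULL)
}

.resnet_stages <- function(depth) {
  switch(depth,
    tiny = list(stem = c(ch = 8L, k = 5L, stride = 2L),
                blocks = "basic", counts = c(1L, 1L, 1L),
                chans = c(16L, 32L, 64L)),
    `18` = list(stem = c(ch = 64L, k = 7L, stride = 2L),
                blocks = "basic", counts = c(2L, 2L, 2L, 2L),
                chans = c(64L, 128L, 256L, 512L)),
    `34` = list(stem = c(ch = 64L, k = 7L, stride = 2L),
                blocks = "basic", counts = c(3L, 4L, 6L, 3L),
                chans = c(64L, 128L, 256L, 512L)),
    `50` = list(stem = c(ch = 64L, k = 7L, stride = 2L),
                blocks = "bottleneck", counts = c(3L, 4L, 6L, 3L),
                chans = c(64L, 128L, 256L, 512L)),
    `101` = list(stem = c(ch = 64L, k = 7L, stride = 2L),
                 blocks = "bottleneck", counts = c(3L, 4L, 23L, 3L),
                 chans = c(64L, 128L, 256L, 512L)))
}

#' Build an untrained regression network
#'
#' Residual CNN over single-channel square images: a strided stem
#' convolution, basic (18/34/tiny) or bottleneck (50/101) residual
#' stages, then the MLP head
#' (1000-512-128-output by default) applied to the flattened final
#' feature maps, with ReLU hidden activations, dropout, and a linear
#' output layer sized by the target type.
#'
#' @param config A [network_config()].
#' @param input_size Image side L in pixels.
#' @return An object of class `nmaflex_network`.
#' @export
build_model <- function(config, input_size) {
  stopifnot(inherits(config, "network_config"))
  set.seed(config$seed)
  arch <- .resnet_stages(config$depth)
  stages <- list()
  stem <- arch$stem
  stages[[1]] <- list(kind = "plain",
                      layers = list(.layer_conv(stem["k"], 1L,
                                                stem["ch"],
                                                stem["stride"]),
                                    .layer_bn(stem["ch"]),
                                    .layer_relu()))
  cin <- stem[["ch"]]
  for (s in seq_along(arch$counts)) {
    for (b in seq_len(arch$counts[s])) {
      stride <- if (b == 1L) 2L else 1L
      if (arch$blocks == "basic") {
        stages[[length(stages) + 1L]] <-
          .basic_block(cin, arch$chans[s], stride)
        cin <- arch$chans[s]
      } else {
        stages[[length(stages) + 1L]] <-
          .bottleneck_block(cin, arch$chans[s], stride)
        cin <- 4L * arch$chans[s]
      }
    }
  }
  stages[[length(stages) + 1L]] <- list(kind = "flatten")
  ## stem + one stride-2 block per stage, each mapping L -> ceil(L/2)
  spatial <- input_size
  for (i in seq_len(1L + length(arch$counts)))
    spatial <- as.integer(ceiling(spatial / 2))
  if (spatial < 1L)
    stop("input_size too small for this depth")
  fin <- cin * spatial^2
  for (wd in config$head_widths) {
    stages[[length(stages) + 1L]] <-
      list(kind = "dense",
           layer = .layer_dense(fin, wd, "relu", config$dropout))
    fin <- wd
  }
  stages[[length(stages) + 1L]] <-
    list(kind = "dense",
         layer = .layer_dense(fin, config$output_dim, "linear", 0))
  structure(list(stages = stages, config = config,
                 input_size = as.integer(input_size)),
            class = "nmaflex_network")
}

#' @export
print.nmaflex_network <- function(x, ...) {
  nres <- sum(vapply(x$stages, function(s) s$kind == "res", logical(1)))
  cat(sprintf(
    "nmaflex_network: depth %s (%d residual blocks), %d x %d input, %s head (%d outputs)\n",
    x$config$depth, nres, x$input_size, x$input_size,
    paste(x$config$head_widths, collapse = "-"), x$config$output_dim))
  invisible(x)
}

# ---------------------------------------------------------------------
# Forward / backward over the stage list

.forward_net <- function(net, x, training = FALSE, rng_dropout = TRUE) {
  caches <- vector("list", length(net$stages))
  for (i in seq_along(net$stages)) {
    st <- net$stages[[i]]
    if (st$kind == "plain") {
      cc <- vector("list", length(st$layers))
      for (j in seq_along(st$layers)) {
        r <- .fwd_layer(st$layers[[j]], x, training)
        x <- r$y
        cc[[j]] <- r$cache
      }
      caches[[i]] <- cc
    } else if (st$kind == "res") {
      x_in <- x
      cc <- list(main = vector("list", length(st$main)))
      for (j in seq_along(st$main)) {
        r <- .fwd_layer(st$main[[j]], x, training)
        x <- r$y
        cc$main[[j]] <- r$cache
      }
      if (!is.null(st$short)) {
        xs <- x_in
        cc$short <- vector("list", length(st$short))
        for (j in seq_along(st$short)) {
          r <- .fwd_layer(st$short[[j]], xs, training)
          xs <- r$y
          cc$short[[j]] <- r$cache
        }
      } else xs <- x_in
      x <- cpp_add_relu(x, xs)
      cc$relu <- x
      caches[[i]] <- cc
    } else if (st$kind == "flatten") {
      d <- dim(x)
      caches[[i]] <- d
      x <- matrix(x, d[1] * d[2] * d[3], d[4])
    } else if (st$kind == "dense") {
      ly <- st$layer
      pre <- ly$w %*% x + ly$b
      if (ly$activation == "relu") {
        mask <- pre > 0
        act <- pre
        act[!mask] <- 0
      } else {
        mask <- NULL
        act <- pre
      }
      dmask <- NULL
      if (training && ly$dropout > 0 && rng_dropout) {
        dmask <- matrix(stats::runif(length(act)) >= ly$dropout,
                        nrow(act), ncol(act))
        act <- act * dmask / (1 - ly$dropout)
      }
      caches[[i]] <- list(x = x, mask = mask, dmask = dmask)
      x <- act
    }
  }
  list(y = x, caches = caches)
}

.backward_net <- function(net, caches, dy) {
  grads <- vector("list", length(net$stages))
  for (i in rev(seq_along(net$stages))) {
    st <- net$stages[[i]]
    cc <- caches[[i]]
    if (st$kind == "plain") {
      gg <- vector("list", length(st$layers))
      for (j in rev(seq_along(st$layers))) {
        r <- .bwd_layer(st$layers[[j]], cc[[j]], dy)
        dy <- r$dx
        gg[j] <- list(r$grads)
      }
      grads[[i]] <- gg
    } else if (st$kind == "res") {
      dy <- cpp_relu_backward(cc$relu, dy)
      dmain <- dy
      gg <- list(main = vector("list", length(st$main)))
      for (j in rev(seq_along(st$main))) {
        r <- .bwd_layer(st$main[[j]], cc$main[[j]], dmain)
        dmain <- r$dx
        gg$main[j] <- list(r$grads)
      }
      if (!is.null(st$short)) {
        dshort <- dy
        gg$short <- vector("list", length(st$short))
        for (j in rev(seq_along(st$short))) {
          r <- .bwd_layer(st$short[[j]], cc$short[[j]], dshort)
          dshort <- r$dx
          gg$short[j] <- list(r$grads)
        }
      } else dshort <- dy
      dy <- dmain + dshort
      grads[[i]] <- gg
    } else if (st$kind == "flatten") {
      dy <- array(dy, dim = cc)
    } else if (st$kind == "dense") {
      ly <- st$layer
      if (!is.null(cc$dmask)) dy <- dy * cc$dmask / (1 - ly$dropout)
      if (!is.null(cc$mask)) dy[!cc$mask] <- 0
      grads[[i]] <- list(w = tcrossprod(dy, cc$x), b = rowSums(dy))
      dy <- crossprod(ly$w, dy)
    }
  }
  grads
}

## walk (stages, grads) applying f(layer, grad) -> layer
.map_layers <- function(net, grads, f) {
  for (i in seq_along(net$stages)) {
    st <- net$stages[[i]]
    if (st$kind == "plain") {
      for (j in seq_along(st$layers))
        net$stages[[i]]$layers[[j]] <-
          f(st$layers[[j]], grads[[i]][[j]], c(i, 1L, j))
    } else if (st$kind == "res") {
      for (j in seq_along(st$main))
        net$stages[[i]]$main[[j]] <-
          f(st$main[[j]], grads[[i]]$main[[j]], c(i, 2L, j))
      if (!is.null(st$short))
        for (j in seq_along(st$short))
          net$stages[[i]]$short[[j]] <-
            f(st$short[[j]], grads[[i]]$short[[j]], c(i, 3L, j))
    } else if (st$kind == "dense") {
      lg <- grads[[i]]
      net$stages[[i]]$layer <- f(st$layer, lg, c(i, 4L, 1L))
    }
  }
  net
}

# ---------------------------------------------------------------------
# Training

.adam_update <- function(layer, grad, key, state, lr, wd, beta1, beta2,
                         eps, t) {
  if (is.null(grad)) return(list(layer = layer, state = state))
  for (pname in names(grad)) {
    id <- paste(c(key, pname), collapse = ".")
    st <- state[[id]]
    r <- cpp_adam_step(layer[[pname]], grad[[pname]],
                       st$m, st$v, lr,
                       if (pname == "w") wd else 0,
                       beta1, beta2, eps, t)
    state[[id]] <- list(m = r$m, v = r$v)
    layer[[pname]] <- r$p
  }
  list(layer = layer, state = state)
}

.prep_images <- function(images) {
  ## per-image standardization (mean 0, sd 1)
  d <- dim(images)
  m <- matrix(images, d[1] * d[2], d[3])
  mu <- colMeans(m)
  sdv <- sqrt(colMeans(m^2) - mu^2)
  sdv[sdv < 1e-12] <- 1
  m <- sweep(sweep(m, 2, mu), 2, sdv, "/")
  array(m, dim = c(d[1], d[2], 1L, d[3]))
}

.fit_scalers <- function(labels, target_type) {
  if (target_type == "quaternion")
    return(list(mean = rep(0, ncol(labels)), sd = rep(1, ncol(labels))))
  mu <- colMeans(labels)
  sdv <- apply(labels, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  list(mean = mu, sd = sdv)
}

.apply_scalers <- function(labels, sc)
  sweep(sweep(labels, 2, sc$mean), 2, sc$sd, "/")

.invert_scalers <- function(labels, sc)
  sweep(sweep(labels, 2, sc$sd, "*"), 2, sc$mean, "+")

.canonicalize_rows <- function(q) {
  t(apply(q, 1, function(v) {
    n <- sqrt(sum(v^2))
    if (n < 1e-12) c(1, 0, 0, 0) else quaternion_canonicalize(v / n)
  }))
}

#' Train a regression network
#'
#' Standardizes targets on the training labels only (quaternions are
#' exempt and instead sign-canonicalized), then runs minibatch Adam on
#' the MAE loss with the configured schedule.  Per-epoch training and
#' validation MAE (in original target units) are logged and the
#' weights of the best-validation epoch are retained.  Deterministic
#' given `config$seed`.
#'
#' @param model An untrained [build_model()] network.
#' @param images L x L x K training image array.
#' @param labels K x D numeric label matrix (provenance: alignment
#'   output or ground truth).
#' @param val_images,val_labels Validation set (required: model
#'   selection is part of the protocol).
#' @param config Optional [network_config()] override (defaults to the
#'   model's).
#' @param verbose Print per-epoch losses.
#' @return An object of class `trained_network`: `net` (best weights),
#'   `scalers`, `training_log` (data frame epoch/train_mae/val_mae),
#'   `config`.
#' @export
train_network <- function(model, images, labels, val_images,
                          val_labels, config = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "nmaflex_network"))
  config <- config %||% model$config
  if (is.null(val_images) || length(val_images) == 0L ||
      dim(val_images)[3] == 0L)
    stop("validation set must be non-empty (used for model selection)")
  labels <- as.matrix(labels)
  val_labels <- as.matrix(val_labels)
  if (config$target_type == "quaternion") {
    labels <- .canonicalize_rows(labels)
    val_labels <- .canonicalize_rows(val_labels)
  }
  sc <- .fit_scalers(labels, config$target_type)
  t_std <- .apply_scalers(labels, sc)
  x_all <- .prep_images(images)
  xv <- .prep_images(val_images)
  k <- dim(images)[3]
  net <- model
  adam_state <- list()
  set.seed(config$seed)
  tstep <- 0L
  log <- data.frame(epoch = integer(0), train_mae = numeric(0),
                    val_mae = numeric(0))
  best <- list(val = Inf, net = net)
  nb <- ceiling(k / config$batch_size)
  for (epoch in seq_len(config$epochs)) {
    lr <- config$lr0 / 10^((epoch - 1) %/% config$lr_decay_every)
    perm <- sample.int(k)
    tr_abs <- 0
    for (bi in seq_len(nb)) {
      idx <- perm[((bi - 1L) * config$batch_size + 1L):
                    min(bi * config$batch_size, k)]
      xb <- x_all[, , , idx, drop = FALSE]
      tb <- t_std[idx, , drop = FALSE]
      fw <- .forward_net(net, xb, training = TRUE)
      err <- t(fw$y) - tb                      # B x D
      tr_abs <- tr_abs + sum(abs(err) %*% sc$sd) / ncol(tb)
      dy <- t(sign(err)) / length(err)         # d(MAE)/dy, D x B
      grads <- .backward_net(net, fw$caches, dy)
      tstep <- tstep + 1L
      net <- .update_bn_from_caches(net, fw$caches)
      net <- .map_layers(net, grads, function(layer, grad, key) {
        r <- .adam_update(layer, grad, key, adam_state, lr,
                          config$weight_decay, 0.9, 0.999, 1e-8, tstep)
        adam_state <<- r$state
        r$layer
      })
    }
    tr_mae <- tr_abs / k
    pv <- .predict_raw(net, xv)
    val_pred <- .invert_scalers(t(pv), sc)
    if (config$target_type == "quaternion")
      val_pred <- .canonicalize_rows(val_pred)
    val_mae <- mean(abs(val_pred - val_labels))
    log <- rbind(log, data.frame(epoch = epoch, train_mae = tr_mae,
                                 val_mae = val_mae))
    if (val_mae < best$val) best <- list(val = val_mae, net = net)
    if (verbose)
      message(sprintf("epoch %3d  lr %.2g  train MAE %.4g  val MAE %.4g",
                      epoch, lr, tr_mae, val_mae))
  }
  structure(list(net = best$net, scalers = sc, training_log = log,
                 config = config, input_size = model$input_size),
            class = "trained_network")
}

## one eval-mode forward pass, batched to bound memory
.predict_raw <- function(net, x, batch = 64L) {
  k <- dim(x)[4]
  out <- NULL
  for (i0 in seq(1L, k, by = batch)) {
    idx <- i0:min(i0 + batch - 1L, k)
    y <- .forward_net(net, x[, , , idx, drop = FALSE],
                      training = FALSE)$y
    out <- if (is.null(out)) y else cbind(out, y)
  }
  out
}

#' Predict particle parameters with a trained network
#'
#' Runs the network in evaluation mode, de-standardizes amplitude and
#' shift outputs, normalizes and sign-canonicalizes predicted
#' quaternions, and converts them to ZYZ Euler angles for the metadata
#' table.
#'
#' @param trained A `trained_network`.
#' @param images L x L x K array (L must match the training size).
#' @return [particle_records()] with provenance `"inferred"`; for
#'   quaternion models the unit quaternions are attached as attribute
#'   `"quaternion"`.
#' @export
predict_network <- function(trained, images) {
  stopifnot(inherits(trained, "trained_network"))
  d <- dim(images)
  if (d[1] != trained$input_size)
    stop(sprintf("image size %d does not match training size %d",
                 d[1], trained$input_size))
  x <- .prep_images(images)
  y <- .invert_scalers(t(.predict_raw(trained$net, x)),
                       trained$scalers)
  k <- nrow(y)
  tt <- trained$config$target_type
  if (tt == "quaternion") {
    q <- .canonicalize_rows(y)
    euler <- t(apply(q, 1, quaternion_to_euler))
    rec <- particle_records(matrix(0, k, 1), euler, matrix(0, k, 2),
                            provenance = "inferred")
    attr(rec, "quaternion") <- q
    rec
  } else if (tt == "shifts") {
    particle_records(matrix(0, k, 1), matrix(0, k, 3), y,
                     provenance = "inferred")
  } else {
    particle_records(y, matrix(0, k, 3), matrix(0, k, 2),
                     provenance = "inferred")
  }
}

#' Split a dataset into train / validation / test subsets
#'
#' Disjoint, reproducible index sets.  With `strata` given (a class
#' label per record) each subset draws uniformly from every class.
#'
#' @param n Number of records (or a [particle_records()] table).
#' @param fractions Named numeric vector summing to at most 1, e.g.
#'   `c(train = 0.2, large_test = 0.714)` for a 20,000 / 50,000 split
#'   of 70,000.
#' @param seed RNG seed.
#' @param strata Optional per-record class labels.
#' @return Named list of integer index vectors (pairwise disjoint).
#' @export
split_dataset <- function(n, fractions, seed = 1L, strata = NULL) {
  if (inherits(n, "data.frame")) n <- nrow(n)
  if (sum(fractions) > 1 + 1e-9) stop("fractions must sum to <= 1")
  if (is.null(names(fractions)) || any(!nzchar(names(fractions))))
    stop("fractions must be named")
  set.seed(seed)
  if (is.null(strata)) {
    perm <- sample.int(n)
    sizes <- floor(fractions * n)
    out <- list()
    at <- 0L
    for (i in seq_along(sizes)) {
      out[[names(fractions)[i]]] <-
        sort(perm[seq_len(sizes[i]) + at])
      at <- at + sizes[i]
    }
  } else {
    stopifnot(length(strata) == n)
    out <- stats::setNames(
      rep(list(integer(0)), length(fractions)), names(fractions))
    for (cl in unique(strata)) {
      idx <- which(strata == cl)
      sub <- split_dataset(length(idx), fractions, seed = seed)
      for (nm in names(fractions))
        out[[nm]] <- sort(c(out[[nm]], idx[sub[[nm]]]))
    }
  }
  stopifnot(!anyDuplicated(unlist(out)))
  out
}

#' Save / load a trained network checkpoint
#'
#' Plain-text checkpoint: a JSON-free, `dput`-based serialization of
#' weights, config and scalers (versioned).
#'
#' @param trained A `trained_network`.
#' @param path File path.
#' @return `load_network`: the `trained_network`.
#' @export
save_network <- function(trained, path) {
  obj <- unclass(trained)
  obj$.format_version <- 1L
  dput(obj, file = path, control = c("all", "hexNumeric"))
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  obj <- dget(path)
  obj$.format_version <- NULL
  structure(obj, class = "trained_network")
}
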