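## Iterative elastic + rigid-body 3D-to-2D alignment.
##
## A deliberately compact re-implementation of the reference-based
## alignment stage: per image, a derivative-free outer loop over
## normal-mode amplitudes wraps an inner rigid alignment (coarse
## orientation grid, FFT cross-correlation translation with sub-pixel
## quadratic refinement, then simplex refinement of all five rigid
## parameters).  The similarity measure is normalized cross-correlation
## (NCC), invariant to the image's global intensity scale.  Images are
## expected phase-flipped beforehand; projections can optionally be
## |CTF|-modulated.

#' Alignment configuration
#'
#' @param angular_grid_step Coarse orientation grid step in degrees,
#'   in (0, 90].
#' @param max_outer_iterations Outer elastic/rigid alternations.
#' @param amplitude_bounds Either a single positive number `A` (every
#'   mode searched in `[-A, A]`) or an M x 2 matrix of per-mode bounds.
#' @param convergence_tol Relative objective change that stops the
#'   outer loop.
#' @param ctf_modulate Multiply projections by |CTF| (needs `ctf` and
#'   `pixel_size` at call time); default off.
#' @param sigma Projection Gaussian width in Angstrom; default
#'   `1.5 * pixel_size` at call time.
#' @param outlier_quantile Records whose final similarity falls below
#'   this quantile of the stack are flagged (feeds the downstream
#'   Mahalanobis filter); default 0.05.
#' @return An object of class `align_config`.
#' @export
align_config <- function(angular_grid_step = 30,
                         max_outer_iterations = 3L,
                         amplitude_bounds = 300,
                         convergence_tol = 1e-4,
                         ctf_modulate = FALSE,
                         sigma = NULL,
                         outlier_quantile = 0.05) {
  if (angular_grid_step <= 0 || angular_grid_step > 90)
    stop("angular_grid_step must be in (0, 90]")
  structure(list(angular_grid_step = angular_grid_step,
                 max_outer_iterations = as.integer(max_outer_iterations),
                 amplitude_bounds = amplitude_bounds,
                 convergence_tol = convergence_tol,
                 ctf_modulate = ctf_modulate, sigma = sigma,
                 outlier_quantile = outlier_quantile),
            class = "align_config")
}

.bounds_matrix <- function(amplitude_bounds, m) {
  if (is.matrix(amplitude_bounds)) {
    stopifnot(nrow(amplitude_bounds) == m, ncol(amplitude_bounds) == 2L)
    amplitude_bounds
  } else cbind(rep(-amplitude_bounds, m), rep(amplitude_bounds, m))
}

.ncc <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

## Best translation of `proj` against `img` by FFT cross-correlation,
## with 3-point parabolic sub-pixel refinement per axis.
.best_shift <- function(img_f, proj, max_shift) {
  L <- nrow(proj)
  cc <- Re(stats::fft(Conj(stats::fft(proj)) * img_f,
                      inverse = TRUE)) / (L * L)
  cc <- .fftshift2(cc)
  c0 <- L / 2 + 1
  win <- (c0 - max_shift):(c0 + max_shift)
  sub <- cc[win, win]
  pk <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  px <- pk[1]; py <- pk[2]
  refine <- function(m1, m2, m3) {
    den <- m1 - 2 * m2 + m3
    if (abs(den) < 1e-12) 0 else 0.5 * (m1 - m3) / den
  }
  dx <- if (px > 1 && px < nrow(sub))
    refine(sub[px - 1, py], sub[px, py], sub[px + 1, py]) else 0
  dy <- if (py > 1 && py < ncol(sub))
    refine(sub[px, py - 1], sub[px, py], sub[px, py + 1]) else 0
  c(win[px] - c0 + dx, win[py] - c0 + dy)
}

#' Align one particle image against the reference
#'
#' Joint estimation of normal-mode amplitudes, ZYZ orientation and
#' in-plane shift by maximizing normalized cross-correlation between
#' the image and projections of the elastically deformed reference.
#' When `init` is supplied (amplitudes, euler, shift) the optimizer
#' starts from it and the returned solution never scores below it.
#'
#' @param image L x L numeric matrix.
#' @param model Reference [coarse_model()].
#' @param modeset `normal_mode_set` used for the elastic deformation.
#' @param config An [align_config()].
#' @param pixel_size Angstrom per pixel.
#' @param ctf Optional [ctf_params()] for projection modulation.
#' @param init Optional list with `amplitudes`, `euler`, `shift`.
#' @return One-row [particle_records()] (provenance `"hemnma"`) with
#'   attributes `similarity` and `converged`.
#' @export
align_image <- function(image, model, modeset, config = align_config(),
                        pixel_size = 1, ctf = NULL, init = NULL) {
  stopifnot(inherits(config, "align_config"))
  L <- nrow(image)
  m <- ncol(modeset$vectors)
  bounds <- .bounds_matrix(config$amplitude_bounds, m)
  sigma <- config$sigma %||% (1.5 * pixel_size)
  max_shift <- floor(L / 4) - 1L
  ctf_mod <- if (config$ctf_modulate && !is.null(ctf))
    abs(.ctf_grid(ctf, L, pixel_size)) else NULL

  proj_fun <- function(q, euler, shift) {
    conf <- apply_amplitudes(model, modeset, q)
    p <- project(conf, euler_to_rotation(euler[1], euler[2], euler[3]),
                 shift, L, pixel_size, sigma = sigma)
    if (!is.null(ctf_mod))
      p <- Re(stats::fft(stats::fft(p) * ctf_mod, inverse = TRUE)) /
        (L * L)
    p
  }
  obj <- function(q, euler, shift) {
    val <- .ncc(image, proj_fun(q, euler, shift))
    if (!is.finite(val))
      stop(sprintf("non-finite similarity at q=(%s) euler=(%s)",
                   paste(signif(q, 4), collapse = ","),
                   paste(signif(euler, 4), collapse = ",")))
    val
  }

  img_f <- stats::fft(image)
  refine5 <- function(q, euler0, shift0) {
    ## simplex refinement of the 5 rigid parameters
    fn <- function(par) -obj(q, par[1:3], par[4:5])
    opt <- stats::optim(c(euler0, shift0), fn, method = "Nelder-Mead",
                        control = list(maxit = 200L,
                                       parscale = c(5, 5, 5, 0.5, 0.5)))
    list(euler = opt$par[1:3], shift = opt$par[4:5], val = -opt$value)
  }
  rigid_align <- function(q, top_k = 6L) {
    ## coarse orientation grid; returns the top_k candidate starts
    step <- config$angular_grid_step
    rots <- seq(0, 360 - step, by = step)
    tilts <- seq(0, 180, by = step)
    psis <- seq(0, 360 - step, by = step)
    conf <- apply_amplitudes(model, modeset, q)
    cand <- list()
    for (tl in tilts) for (rt in rots) for (ps in psis) {
      p <- project(conf, euler_to_rotation(rt, tl, ps), c(0, 0), L,
                   pixel_size, sigma = sigma)
      if (!is.null(ctf_mod))
        p <- Re(stats::fft(stats::fft(p) * ctf_mod,
                           inverse = TRUE)) / (L * L)
      s <- .best_shift(img_f, p, max_shift)
      v <- .ncc(image, proj_fun(q, c(rt, tl, ps), s))
      cand[[length(cand) + 1L]] <- list(val = v,
                                        euler = c(rt, tl, ps),
                                        shift = s)
      if (tl %in% c(0, 180)) break   # psi degenerate at the poles
    }
    vals <- vapply(cand, `[[`, numeric(1), "val")
    cand[order(vals, decreasing = TRUE)[
      seq_len(min(top_k, length(cand)))]]
  }

  ## alternate amplitude line searches with local rigid refinement
  ## from one starting basin
  alternate <- function(q, euler, shift, val) {
    converged <- FALSE
    for (it in seq_len(config$max_outer_iterations)) {
      prev <- val
      for (j in seq_len(m)) {
        line <- function(a) {
          qq <- q; qq[j] <- a
          -obj(qq, euler, shift)
        }
        o <- stats::optimize(line, lower = bounds[j, 1],
                             upper = bounds[j, 2], tol = 1e-2)
        if (-o$objective > val) {
          q[j] <- o$minimum
          val <- -o$objective
        }
      }
      r <- refine5(q, euler, shift)
      if (r$val > val) {
        euler <- r$euler; shift <- r$shift; val <- r$val
      }
      if (abs(val - prev) <
          config$convergence_tol * max(abs(prev), 1e-12)) {
        converged <- TRUE
        break
      }
    }
    list(q = q, euler = euler, shift = shift, val = val,
         converged = converged)
  }

  if (!is.null(init)) {
    ## single basin around the supplied start
    starts <- list(list(euler = init$euler, shift = init$shift))
    q0 <- init$amplitudes
  } else {
    ## beam over the best coarse-grid orientations at q = 0: large
    ## elastic deformations can demote the true basin in the rigid
    ## grid, so several basins are pursued to convergence
    starts <- rigid_align(numeric(m))
    q0 <- numeric(m)
  }
  best <- list(val = -Inf)
  for (s0 in starts) {
    r5 <- refine5(q0, s0$euler, s0$shift)
    a <- alternate(q0, r5$euler, r5$shift, r5$val)
    if (a$val > best$val) best <- a
  }
  q <- best$q; euler <- best$euler; shift <- best$shift
  best_val <- best$val
  converged <- best$converged
  ## final joint polish of all parameters in one simplex
  fn_all <- function(par)
    -obj(par[seq_len(m)], par[m + 1:3], par[m + 4:5])
  opt <- stats::optim(c(q, euler, shift), fn_all,
                      method = "Nelder-Mead",
                      control = list(maxit = 400L,
                                     reltol = 1e-10,
                                     parscale = c(rep(20, m),
                                                  2, 2, 2, 0.3, 0.3)))
  if (-opt$value > best_val) {
    q <- opt$par[seq_len(m)]
    euler <- opt$par[m + 1:3]
    shift <- opt$par[m + 4:5]
    best_val <- -opt$value
  }
  init_val <- if (is.null(init)) -Inf
  else obj(init$amplitudes, init$euler, init$shift)
  ## never return a solution below the supplied starting point
  if (!is.null(init) && init_val > best_val) {
    q <- init$amplitudes; euler <- init$euler; shift <- init$shift
    best_val <- init_val
  }
  euler <- c(euler[1] %% 360, euler[2], euler[3] %% 360)
  if (euler[2] < 0 || euler[2] > 180) {
    ## fold tilt back into [0, 180] through the equivalent triple
    R <- euler_to_rotation(euler[1], euler[2], euler[3])
    euler <- rotation_to_euler(R)
  }
  rec <- particle_records(matrix(q, 1), matrix(euler, 1),
                          matrix(shift, 1),
                          defocus = if (is.null(ctf)) 0 else ctf$defocus_um,
                          provenance = "hemnma")
  attr(rec, "similarity") <- best_val
  attr(rec, "converged") <- converged
  rec
}

#' Align a whole stack
#'
#' Sequential, deterministic map of [align_image()] over the stack
#' (results are independent of `n_workers` by construction; the
#' argument sizes an optional `parallel::mclapply` fan-out whose
#' per-image work is seed-free).  Per-image failures become flagged
#' records (`similarity = NA`) rather than a crash.  Records whose
#' final similarity falls below `config$outlier_quantile` are flagged
#' in the `outlier` attribute.
#'
#' @param stack A [particle_stack()].
#' @param model,modeset,config,ctf See [align_image()].
#' @param n_workers Parallel workers (default 1).
#' @return [particle_records()] with attributes `similarity`,
#'   `converged`, `outlier` (logical vectors).
#' @export
align_stack <- function(stack, model, modeset, config = align_config(),
                        ctf = NULL, n_workers = 1L) {
  stopifnot(inherits(stack, "particle_stack"))
  k <- dim(stack$images)[3]
  if (k == 0L) {
    rec <- particle_records(matrix(0, 0, ncol(modeset$vectors)),
                            matrix(0, 0, 3), matrix(0, 0, 2))
    attr(rec, "similarity") <- numeric(0)
    return(rec)
  }
  one <- function(i) {
    tryCatch(align_image(stack$images[, , i], model, modeset, config,
                         pixel_size = stack$pixel_size, ctf = ctf),
             error = function(e) {
               rec <- particle_records(
                 matrix(NA_real_, 1, ncol(modeset$vectors)),
                 matrix(0, 1, 3), matrix(0, 1, 2),
                 provenance = "hemnma")
               attr(rec, "similarity") <- NA_real_
               attr(rec, "converged") <- FALSE
               rec
             })
  }
  res <- if (n_workers > 1L)
    parallel::mclapply(seq_len(k), one, mc.cores = n_workers)
  else lapply(seq_len(k), one)
  sims <- vapply(res, function(r) attr(r, "similarity"), numeric(1))
  conv <- vapply(res, function(r) isTRUE(attr(r, "converged")),
                 logical(1))
  rec <- do.call(rbind, lapply(res, as.data.frame))
  rec$index <- seq_len(k) - 1L
  class(rec) <- c("particle_records", "data.frame")
  thr <- stats::quantile(sims, config$outlier_quantile, na.rm = TRUE,
                         names = FALSE)
  attr(rec, "similarity") <- sims
  attr(rec, "converged") <- conv
  attr(rec, "outlier") <- is.na(sims) | sims < thr
  rec
}
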