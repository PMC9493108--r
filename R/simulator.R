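## Ground-truth synthetic single-particle generator.
##
## The default configuration reproduces the reference study conditions:
## 256^3 maps / 256 x 256 images at 0.325 Angstrom per pixel,
## conformations along a helical three-mode trajectory sampled through
## a uniform latent r in [0,1], uniform random ZYZ angles
## (rot, psi in [0,360), tilt in [0,180) -- note: angles uniform, not
## orientations uniform on SO(3)), in-plane shifts uniform in +/-5 px,
## a single CTF for the whole dataset (200 kV, Cs 2 mm, defocus
## -0.5 um), noise split before and after the CTF at total SNR 0.1, and
## antialiased 2x Fourier-crop downscaling.

# ---------------------------------------------------------------------
# Trajectory

#' Parametric conformational trajectory specification
#'
#' One amplitude function of the latent coordinate `r` in `[0, 1]` per
#' flexible mode.  The default is the helical reference transition over
#' modes 7-9:
#' `q7(r) = -200 r`, `q8(r) = 200 sin(pi r)`, `q9(r) = 200 cos(pi r)`.
#'
#' @param mode_ids Integer ids of the modes that carry motion.
#' @param amplitude_functions List of functions of `r`, one per mode.
#' @return An object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(mode_ids = 7:9,
                            amplitude_functions = list(
                              function(r) -200 * r,
                              function(r) 200 * sin(pi * r),
                              function(r) 200 * cos(pi * r))) {
  if (length(mode_ids) != length(amplitude_functions))
    stop("one amplitude function per mode id is required")
  structure(list(mode_ids = mode_ids,
                 amplitude_functions = amplitude_functions),
            class = "trajectory_spec")
}

#' Sample ground-truth amplitudes along the trajectory
#'
#' Draws `n` latent coordinates `r ~ U(0, 1)` and evaluates the
#' per-mode amplitude functions at them.
#'
#' @param spec A [trajectory_spec()].
#' @param n Number of samples.
#' @param seed Optional RNG seed.
#' @param r Optional explicit latent coordinates (overrides sampling).
#' @return List with `r` (length n) and `amplitudes` (n x M matrix).
#' @export
sample_trajectory <- function(spec, n, seed = NULL, r = NULL) {
  stopifnot(inherits(spec, "trajectory_spec"))
  if (is.null(r)) {
    if (!is.null(seed)) set.seed(seed)
    r <- stats::runif(n)
  }
  amp <- vapply(spec$amplitude_functions, function(f) f(r),
                numeric(length(r)))
  if (length(r) == 1L) amp <- matrix(amp, nrow = 1L)
  colnames(amp) <- paste0("amp_", seq_along(spec$mode_ids))
  list(r = r, amplitudes = amp)
}

# ---------------------------------------------------------------------
# Rendering and projection

#' Render a point model as a 3D density map
#'
#' Sum of mass-weighted normalized isotropic 3D Gaussians of width
#' `model$gaussian_sigma`, evaluated on the cubic grid; the model
#' origin sits at grid index `size/2`.  Total integrated density
#' (voxel sum times voxel volume) equals the total mass when the
#' support lies fully inside the box.
#'
#' @param model A [coarse_model()].
#' @param size Grid side in voxels.
#' @param voxel_size Angstrom per voxel.
#' @param origin Map origin offset in Angstrom.
#' @return A [density_map()].
#' @export
render_density <- function(model, size, voxel_size,
                           origin = c(0, 0, 0)) {
  stopifnot(inherits(model, "coarse_model"))
  half <- size / 2 * voxel_size
  rel <- sweep(model$coords, 2, origin)
  if (any(abs(rel) > half)) {
    n_out <- sum(apply(abs(rel) > half, 1, any))
    warning(sprintf("%d point(s) extend beyond the grid and are clipped",
                    n_out))
  }
  v <- cpp_render_density(model$coords, model$masses,
                          model$gaussian_sigma, as.integer(size),
                          voxel_size, origin[1], origin[2], origin[3])
  density_map(v, voxel_size, origin)
}

#' Project a model (or map) onto the image plane
#'
#' Default path: rotate the model coordinates by `rotation`, splat each
#' point as the exact line integral along z of its 3D Gaussian (a 2D
#' Gaussian of the same width), then apply the in-plane shift in
#' pixels.  The model origin projects to image center `L/2`.
#'
#' @param model A [coarse_model()].
#' @param rotation 3x3 rotation matrix (see [euler_to_rotation()]).
#' @param shift Length-2 shift `(sx, sy)` in pixels.
#' @param image_size Image side L in pixels.
#' @param pixel_size Angstrom per pixel.
#' @param sigma Gaussian width override (default the model's).
#' @return L x L numeric matrix (first index x, second y).
#' @export
project <- function(model, rotation, shift = c(0, 0), image_size,
                    pixel_size, sigma = NULL) {
  stopifnot(inherits(model, "coarse_model"))
  if (max(abs(shift)) > image_size / 4)
    stop("shifts beyond image_size/4 are not supported")
  if (is.null(sigma)) sigma <- model$gaussian_sigma
  xy <- model$coords %*% t(rotation)
  xy <- xy[, 1:2, drop = FALSE] +
    rep(shift * pixel_size, each = nrow(xy))
  cpp_project_points(xy, model$masses, sigma,
                     as.integer(image_size), pixel_size)
}

#' Volume-path projection (cross-check oracle)
#'
#' Rotates the voxel grid by trilinear interpolation and sums along z
#' (scaled by the voxel size so values approximate line integrals).
#' Slower than [project()]; used to validate it.
#'
#' @param map A [density_map()].
#' @param rotation 3x3 rotation matrix.
#' @return L x L numeric matrix.
#' @export
project_map <- function(map, rotation) {
  stopifnot(inherits(map, "density_map"))
  n <- dim(map$data)[1]
  c0 <- n / 2
  ax <- seq_len(n) - 1 - c0
  g <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  src <- g %*% rotation + c0          # R^T u, in grid units
  sx <- src[, 1]; sy <- src[, 2]; sz <- src[, 3]
  i0 <- floor(sx); j0 <- floor(sy); k0 <- floor(sz)
  fx <- sx - i0; fy <- sy - j0; fz <- sz - k0
  val <- numeric(nrow(src))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    ii <- i0 + dx; jj <- j0 + dy; kk <- k0 + dz
    ok <- ii >= 0 & ii < n & jj >= 0 & jj < n & kk >= 0 & kk < n
    w <- (dx * fx + (1 - dx) * (1 - fx)) *
      (dy * fy + (1 - dy) * (1 - fy)) *
      (dz * fz + (1 - dz) * (1 - fz))
    idx <- ii[ok] + n * (jj[ok] + n * kk[ok]) + 1
    val[ok] <- val[ok] + w[ok] * map$data[idx]
  }
  rot_vol <- array(val, dim = c(n, n, n))
  apply(rot_vol, c(1, 2), sum) * map$voxel_size
}

# ---------------------------------------------------------------------
# CTF

## Relativistic electron wavelength in Angstrom for voltage in kV.
electron_wavelength <- function(voltage_kV) {
  v <- voltage_kV * 1e3
  12.2639 / sqrt(v * (1 + 0.97845e-6 * v))
}

#' Evaluate the contrast transfer function
#'
#' Phase aberration `chi(f) = pi lambda dz f^2 - (pi/2) Cs lambda^3
#' f^4` with the electron wavelength from the relativistic formula;
#' `CTF(f) = -sqrt(1 - w^2) sin(chi) - w cos(chi)` where `w` is the
#' amplitude contrast.  At `f = 0` the value is `-w`.
#'
#' @param ctf A [ctf_params()].
#' @param freq Spatial frequencies in 1/Angstrom (any shape).
#' @return Transfer values with the shape of `freq`.
#' @export
ctf_evaluate <- function(ctf, freq) {
  stopifnot(inherits(ctf, "ctf_params"))
  lambda <- electron_wavelength(ctf$voltage_kV)
  dz <- ctf$defocus_um * 1e4            # um -> Angstrom
  cs <- ctf$cs_mm * 1e7                 # mm -> Angstrom
  chi <- pi * lambda * dz * freq^2 -
    (pi / 2) * cs * lambda^3 * freq^4
  w <- ctf$amplitude_contrast
  -sqrt(1 - w^2) * sin(chi) - w * cos(chi)
}

## 2D CTF grid in R's unshifted FFT layout for an L x L image.
.ctf_grid <- function(ctf, L, pixel_size) {
  f1 <- c(0:(L / 2 - 1), -(L / 2):-1) / (L * pixel_size)
  fr <- sqrt(outer(f1^2, f1^2, "+"))
  ctf_evaluate(ctf, fr)
}

#' Apply a CTF to an image (Fourier multiplication)
#'
#' @param image L x L numeric matrix.
#' @param ctf A [ctf_params()].
#' @param pixel_size Angstrom per pixel.
#' @return Filtered image.
#' @export
ctf_apply <- function(image, ctf, pixel_size) {
  h <- .ctf_grid(ctf, nrow(image), pixel_size)
  Re(stats::fft(stats::fft(image) * h, inverse = TRUE)) /
    length(image)
}

#' Phase-flip an image (CTF sign correction)
#'
#' Multiplies the image spectrum by `sign(CTF)`, so that a CTF-affected
#' image acquires the non-negative transfer `|CTF|`.  The result
#' carries the attribute `phase_flipped = TRUE` and an already-flipped
#' image is returned unchanged, making the correction idempotent (the
#' effective transfer after flipping is `|CTF|`, whose sign is +1
#' everywhere).
#'
#' @inheritParams ctf_apply
#' @return Phase-flipped image.
#' @export
phase_flip <- function(image, ctf, pixel_size) {
  if (isTRUE(attr(image, "phase_flipped"))) return(image)
  h <- sign(.ctf_grid(ctf, nrow(image), pixel_size))
  out <- Re(stats::fft(stats::fft(image) * h, inverse = TRUE)) /
    length(image)
  attr(out, "phase_flipped") <- TRUE
  out
}

# ---------------------------------------------------------------------
# Noise

#' Add two-stage noise at a target SNR
#'
#' White Gaussian noise is split into a pre-CTF component (fraction
#' `pre_ctf_fraction` of the total noise variance, filtered by the CTF
#' together with the signal) and a post-CTF white component.  The total
#' noise variance is set so that `var(signal) / var(noise) = snr`,
#' where the signal variance is measured over the particle support
#' mask (pixels above 1% of the clean image maximum) unless
#' `full_frame = TRUE`.  The pre-CTF component is pre-scaled by the
#' CTF's mean power so its post-filter variance meets its share.
#'
#' @param image Clean L x L projection (before CTF).
#' @param snr Target signal-to-noise variance ratio (> 0).
#' @param pre_ctf_fraction Fraction `p` of noise variance added before
#'   the CTF (default 0.5; ignored when `ctf` is NULL).
#' @param ctf A [ctf_params()] or NULL for no CTF.
#' @param pixel_size Angstrom per pixel.
#' @param full_frame Measure signal variance over the full frame
#'   instead of the support mask.
#' @return Noisy (and, when `ctf` is given, CTF-modulated) image.
#' @export
add_noise <- function(image, snr, pre_ctf_fraction = 0.5, ctf = NULL,
                      pixel_size = 1, full_frame = FALSE) {
  if (snr <= 0) stop("snr must be > 0")
  L <- nrow(image)
  support <- if (full_frame) rep(TRUE, length(image))
  else abs(image) > 0.01 * max(abs(image))
  v_sig <- stats::var(as.numeric(image[support]))
  v_tot <- v_sig / snr
  p <- if (is.null(ctf)) 0 else pre_ctf_fraction
  if (p > 0) {
    h2 <- mean(.ctf_grid(ctf, L, pixel_size)^2)
    n1 <- matrix(stats::rnorm(L * L, sd = sqrt(p * v_tot / h2)), L, L)
    image <- image + n1
  }
  if (!is.null(ctf)) image <- ctf_apply(image, ctf, pixel_size)
  if (p < 1) {
    n2 <- matrix(stats::rnorm(L * L, sd = sqrt((1 - p) * v_tot)), L, L)
    image <- image + n2
  }
  image
}

# ---------------------------------------------------------------------
# Downscaling

.fftshift2 <- function(m) {
  n <- nrow(m)
  h <- n / 2
  m[c((h + 1):n, 1:h), c((h + 1):n, 1:h)]
}

#' Antialiased downscaling by Fourier cropping
#'
#' Low-pass filters at the new Nyquist frequency
#' `1 / (2 * factor * pixel_size)` (for the reference 0.325 Angstrom
#' pixels and factor 2 this is the 1.3 Angstrom cutoff) and crops the
#' centered spectrum to `L / factor`.  DC is preserved exactly.
#'
#' @param image L x L numeric matrix (L divisible by `2 * factor`).
#' @param factor Integer downscaling factor (1, 2 or 4).
#' @return `(L/factor)` square matrix.
#' @export
downscale <- function(image, factor) {
  if (factor == 1) return(image)
  if (!factor %in% c(2L, 4L)) stop("downscale factor must be 1, 2 or 4")
  L <- nrow(image)
  if (L %% (2L * factor) != 0L)
    stop("image side must be divisible by twice the factor")
  Ln <- L %/% factor
  fs <- .fftshift2(stats::fft(image))
  c0 <- L / 2 + 1
  keep <- (c0 - Ln / 2):(c0 + Ln / 2 - 1)
  small <- .fftshift2(fs[keep, keep])
  Re(stats::fft(small, inverse = TRUE)) / (L * L)
}

#' Downscale a whole particle stack
#'
#' Applies [downscale()] per image, multiplies the pixel size by the
#' factor and divides the stored shifts by it (so that reconstructing
#' from the original images requires multiplying them back).
#'
#' @param stack A [particle_stack()].
#' @param factor Downscaling factor.
#' @return The downscaled [particle_stack()].
#' @export
downscale_stack <- function(stack, factor) {
  stopifnot(inherits(stack, "particle_stack"))
  if (factor == 1) return(stack)
  d <- dim(stack$images)
  Ln <- d[1] %/% factor
  imgs <- array(0, dim = c(Ln, Ln, d[3]))
  for (k in seq_len(d[3]))
    imgs[, , k] <- downscale(stack$images[, , k], factor)
  rec <- stack$records
  rec$sx <- rec$sx / factor
  rec$sy <- rec$sy / factor
  particle_stack(imgs, stack$pixel_size * factor, rec)
}

# ---------------------------------------------------------------------
# Dataset simulation

#' Simulation configuration
#'
#' Defaults are the reference synthetic-study conditions: 256 px
#' images at 0.325 Angstrom, shifts uniform in +/-5 px, SNR 0.1 with
#' the noise variance split evenly before/after the CTF, a 200 kV /
#' Cs 2 mm / defocus -0.5 um CTF, and 2x downscaling.
#'
#' @param map_size Map/image side in voxels/pixels.
#' @param pixel_size Angstrom per pixel.
#' @param n_particles Number of images to synthesise.
#' @param shift_range Shifts drawn uniformly in `[-shift_range,
#'   shift_range]` pixels.
#' @param snr Signal-to-noise variance ratio; `Inf` disables noise.
#' @param pre_ctf_noise_fraction Fraction of noise variance added
#'   before the CTF.
#' @param ctf A [ctf_params()] or NULL to disable the CTF.
#' @param downscale_factor 1, 2 or 4.
#' @param gaussian_sigma Rendering width in Angstrom (default
#'   `1.5 * pixel_size`, resolution-limited rendering).
#' @param seed RNG seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(map_size = 256L, pixel_size = 0.325,
                       n_particles = 70000L, shift_range = 5,
                       snr = 0.1, pre_ctf_noise_fraction = 0.5,
                       ctf = ctf_params(), downscale_factor = 2L,
                       gaussian_sigma = 1.5 * pixel_size,
                       seed = 1L) {
  if (!is.infinite(snr) && snr <= 0) stop("snr must be > 0")
  if (shift_range < 0) stop("shift_range must be >= 0")
  if (!downscale_factor %in% c(1L, 2L, 4L))
    stop("downscale_factor must be 1, 2 or 4")
  structure(list(map_size = as.integer(map_size),
                 pixel_size = pixel_size,
                 n_particles = as.integer(n_particles),
                 shift_range = shift_range, snr = snr,
                 pre_ctf_noise_fraction = pre_ctf_noise_fraction,
                 ctf = ctf, downscale_factor = as.integer(downscale_factor),
                 gaussian_sigma = gaussian_sigma, seed = seed),
            class = "sim_config")
}

#' Synthesise a ground-truth particle dataset
#'
#' Per particle: sample the latent `r` and mode amplitudes from the
#' trajectory, deform the reference model, project at uniform random
#' ZYZ angles (`rot, psi ~ U[0, 360)`, `tilt ~ U[0, 180)`) and uniform
#' shifts, apply the CTF, add two-stage noise, then downscale.  All
#' ground-truth parameters are recorded with provenance
#' `"ground_truth"` (shifts stored at the delivered scale).
#'
#' @param model Reference [coarse_model()].
#' @param modeset `normal_mode_set` whose columns match
#'   `spec$mode_ids`.
#' @param spec A [trajectory_spec()].
#' @param config A [sim_config()].
#' @return A [particle_stack()]; the latent coordinates are attached as
#'   attribute `"r"`.
#' @export
simulate_dataset <- function(model, modeset, spec, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_particles
  traj <- sample_trajectory(spec, n)
  euler <- cbind(rot = stats::runif(n, 0, 360),
                 tilt = stats::runif(n, 0, 180),
                 psi = stats::runif(n, 0, 360))
  shift <- cbind(sx = stats::runif(n, -config$shift_range,
                                   config$shift_range),
                 sy = stats::runif(n, -config$shift_range,
                                   config$shift_range))
  L <- config$map_size
  imgs <- array(0, dim = c(L, L, n))
  sig <- config$gaussian_sigma
  for (k in seq_len(n)) {
    conf <- apply_amplitudes(model, modeset, traj$amplitudes[k, ])
    R <- euler_to_rotation(euler[k, 1], euler[k, 2], euler[k, 3])
    img <- project(conf, R, shift[k, ], L, config$pixel_size,
                   sigma = sig)
    if (!is.infinite(config$snr)) {
      img <- add_noise(img, config$snr,
                       config$pre_ctf_noise_fraction, config$ctf,
                       config$pixel_size)
    } else if (!is.null(config$ctf)) {
      img <- ctf_apply(img, config$ctf, config$pixel_size)
    }
    imgs[, , k] <- img
  }
  defocus <- if (is.null(config$ctf)) 0 else config$ctf$defocus_um
  rec <- particle_records(traj$amplitudes, euler, shift,
                          defocus = defocus,
                          provenance = "ground_truth")
  stack <- particle_stack(imgs, config$pixel_size, rec)
  stack <- downscale_stack(stack, config$downscale_factor)
  attr(stack, "r") <- traj$r
  stack
}
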