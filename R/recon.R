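## Direct Fourier-inversion 3D reconstruction, Fourier shell
## correlation, and the per-parameter-type evaluation report.
##
## Each image's 2D FFT is shift-corrected by a Fourier phase ramp and
## inserted as a central slice oriented by the particle rotation, with
## trilinear gridding and sampling-weight normalization.  Inputs are
## assumed phase-flipped; no CTF correction happens here.  The absolute
## intensity scale of the reconstruction is arbitrary.

.fftshift3 <- function(a) {
  n <- dim(a)[1]
  h <- n / 2
  idx <- c((h + 1):n, 1:h)
  a[idx, idx, idx]
}

#' Reconstruct a 3D map from posed particle images
#'
#' @param stack A [particle_stack()] (or plain L x L x K array with
#'   `pixel_size` given).
#' @param records [particle_records()] carrying Euler angles (degrees)
#'   and shifts (pixels) for every image; defaults to the stack's own.
#' @param pixel_size Override for plain arrays.
#' @param weight_floor Fourier bins with accumulated gridding weight
#'   below this are zeroed instead of divided (default 0.2).
#' @return A [density_map()] on the L^3 grid of the images.
#' @export
reconstruct <- function(stack, records = NULL, pixel_size = NULL,
                        weight_floor = 0.2) {
  if (inherits(stack, "particle_stack")) {
    imgs <- stack$images
    if (is.null(records)) records <- stack$records
    pixel_size <- stack$pixel_size
  } else imgs <- stack
  d <- dim(imgs)
  if (is.null(d) || length(d) != 3L || d[3] < 1L)
    stop("cannot reconstruct from an empty image group")
  L <- d[1]
  if (nrow(records) != d[3])
    stop("records do not match the image count")
  euler <- records_euler(records)
  shift <- records_shift(records)
  u <- c(0:(L / 2 - 1), -(L / 2):-1)
  ## the object sits at pixel L/2, so the raw DFT oscillates by
  ## (-1)^k; de-modulate to the centered DFT (smooth in k) before
  ## interpolating between Fourier samples, re-modulate afterwards
  cb1 <- (-1)^(0:(L - 1))
  cb2 <- outer(cb1, cb1)
  fimg <- array(complex(real = 0), dim = d)
  rots <- array(0, dim = c(3, 3, d[3]))
  for (k in seq_len(d[3])) {
    f <- stats::fft(imgs[, , k]) * cb2
    ## undo the in-plane translation: phase ramp exp(+2 pi i u.s / L)
    ramp <- exp(2i * pi * (outer(u * shift[k, 1], u * shift[k, 2],
                                 "+")) / L)
    fimg[, , k] <- .fftshift2(f * ramp)
    rots[, , k] <- euler_to_rotation(euler[k, 1], euler[k, 2],
                                     euler[k, 3])
  }
  ins <- cpp_insert_slices(fimg, rots)
  w <- ins$weight
  f3 <- ins$numerator
  f3[w > weight_floor] <- f3[w > weight_floor] / w[w > weight_floor]
  f3[w <= weight_floor] <- 0
  f3 <- .fftshift3(f3) * outer(cb2, cb1)
  vol <- Re(stats::fft(f3, inverse = TRUE)) / L^3
  density_map(vol, pixel_size %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fourier shell correlation between two maps
#'
#' Per-shell (width one Fourier voxel) normalized cross-correlation of
#' the Fourier coefficients of two maps on the same grid.
#'
#' @param map_a,map_b [density_map()]s with identical grid and voxel
#'   size.
#' @return An object of class `fsc_curve` with `shell_freqs` (1/
#'   Angstrom), `correlations`, and the grid metadata.
#' @export
fsc <- function(map_a, map_b) {
  stopifnot(inherits(map_a, "density_map"),
            inherits(map_b, "density_map"))
  if (!identical(dim(map_a$data), dim(map_b$data)) ||
      abs(map_a$voxel_size - map_b$voxel_size) > 1e-9)
    stop("FSC requires identical grids and voxel sizes")
  n <- dim(map_a$data)[1]
  fa <- .fftshift3(stats::fft(map_a$data))
  fb <- .fftshift3(stats::fft(map_b$data))
  c0 <- n / 2
  ax <- (seq_len(n) - 1 - c0)
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  shell <- pmin(round(sqrt(r2)), c0)
  nshell <- c0 + 1L
  cross <- Re(fa * Conj(fb))
  pa <- Mod(fa)^2
  pb <- Mod(fb)^2
  s_cross <- vapply(0:(nshell - 1L),
                    function(s) sum(cross[shell == s]), numeric(1))
  s_pa <- vapply(0:(nshell - 1L),
                 function(s) sum(pa[shell == s]), numeric(1))
  s_pb <- vapply(0:(nshell - 1L),
                 function(s) sum(pb[shell == s]), numeric(1))
  corr <- s_cross / sqrt(pmax(s_pa * s_pb, .Machine$double.xmin))
  structure(list(shell_freqs = (0:(nshell - 1L)) /
                   (n * map_a$voxel_size),
                 correlations = corr, n = n,
                 voxel_size = map_a$voxel_size),
            class = "fsc_curve")
}

#' @export
print.fsc_curve <- function(x, ...) {
  cat(sprintf("fsc_curve: %d shells to %.4g 1/A\n",
              length(x$correlations), max(x$shell_freqs)))
  cat(sprintf("resolution at 0.5: %.3g A; at 0.143: %.3g A\n",
              fsc_resolution(x, 0.5), fsc_resolution(x, 0.143)))
  invisible(x)
}

#' Resolution at an FSC threshold
#'
#' The frequency of the first crossing below the threshold (linear
#' interpolation between shells), reported as 1/frequency in Angstrom;
#' `Inf`-free: if the curve never drops below the threshold the Nyquist
#' resolution (2 x voxel size) is returned.
#'
#' @param curve An `fsc_curve`.
#' @param threshold FSC threshold (e.g. 0.5 or 0.143).
#' @return Resolution in Angstrom.
#' @export
fsc_resolution <- function(curve, threshold = 0.5) {
  corr <- curve$correlations
  f <- curve$shell_freqs
  below <- which(corr < threshold)
  below <- below[below > 1L]
  if (length(below) == 0L) return(2 * curve$voxel_size)
  i <- below[1L]
  ## linear interpolation between shells i-1 and i
  f_cross <- f[i - 1] + (f[i] - f[i - 1]) *
    (corr[i - 1] - threshold) / (corr[i - 1] - corr[i])
  1 / f_cross
}

# ---------------------------------------------------------------------
# Evaluation metrics

#' Compare predicted and reference particle parameters
#'
#' Produces the standard error report: per-mode and mean-over-modes
#' amplitude mean absolute error, mean axis-based angular distance
#' (see [angular_distance()]), per-axis shift MAE in Angstrom, and
#' three RMSD summaries obtained by displacing the reference model
#' with one parameter type at a time (amplitudes / rotations about the
#' model centroid / translations), each averaged over images with its
#' standard deviation.
#'
#' @param records_pred,records_truth Index-aligned
#'   [particle_records()] tables.
#' @param model Reference [coarse_model()].
#' @param modeset `normal_mode_set` matching the amplitude columns.
#' @param pixel_size Angstrom per pixel (for shifts in Angstrom).
#' @return An object of class `nmaflex_evaluation` (a list of metric
#'   blocks) with a printed table layout.
#' @export
evaluate_predictions <- function(records_pred, records_truth, model,
                                 modeset, pixel_size = 1) {
  if (nrow(records_pred) != nrow(records_truth))
    stop("record sets differ in length")
  k <- nrow(records_pred)
  qp <- records_amplitudes(records_pred)
  qt <- records_amplitudes(records_truth)
  if (ncol(qp) != ncol(qt)) stop("amplitude dimensions differ")
  ep <- records_euler(records_pred)
  et <- records_euler(records_truth)
  sp <- records_shift(records_pred)
  st <- records_shift(records_truth)
  n <- nrow(model$coords)
  x0 <- sweep(model$coords, 2, colMeans(model$coords))

  amp_err <- abs(qp - qt)
  ang <- numeric(k)
  rmsd_ang <- numeric(k)
  for (i in seq_len(k)) {
    rp <- euler_to_rotation(ep[i, 1], ep[i, 2], ep[i, 3])
    rt <- euler_to_rotation(et[i, 1], et[i, 2], et[i, 3])
    ang[i] <- angular_distance(rp, rt)
    rmsd_ang[i] <- sqrt(mean(rowSums((x0 %*% t(rp) - x0 %*% t(rt))^2)))
  }
  dq <- qp - qt
  ## amplitude RMSD: |V dq| / sqrt(N) with unit-norm mode columns V
  rmsd_amp <- vapply(seq_len(k), function(i)
    sqrt(sum((modeset$vectors %*% dq[i, ])^2) / n), numeric(1))
  ds <- (sp - st) * pixel_size
  rmsd_shift <- sqrt(rowSums(ds^2))

  msd <- function(v) c(mean = mean(v), sd = stats::sd(v))
  structure(list(
    n_images = k,
    amplitude_mae = list(
      per_mode = apply(amp_err, 2, msd),
      over_modes = msd(rowMeans(amp_err))),
    angular = msd(ang),
    shift_mae_A = list(x = msd(abs(ds[, 1])), y = msd(abs(ds[, 2]))),
    rmsd = list(amplitudes = msd(rmsd_amp), angles = msd(rmsd_ang),
                shifts = msd(rmsd_shift))),
    class = "nmaflex_evaluation")
}

#' @export
print.nmaflex_evaluation <- function(x, ...) {
  f <- function(v) sprintf("%.3g (sd %.3g)", v["mean"], v["sd"])
  cat(sprintf("Parameter errors over %d images\n", x$n_images))
  cat("  amplitude MAE, mean over modes:",
      f(x$amplitude_mae$over_modes), "\n")
  pm <- x$amplitude_mae$per_mode
  for (j in seq_len(ncol(pm)))
    cat(sprintf("    mode %d: %s\n", j, f(pm[, j])))
  cat("  angular distance [deg]:", f(x$angular), "\n")
  cat("  shift MAE [A]: x", f(x$shift_mae_A$x),
      " y", f(x$shift_mae_A$y), "\n")
  cat("  RMSD [A]: amplitudes", f(x$rmsd$amplitudes),
      "| angles", f(x$rmsd$angles),
      "| shifts", f(x$rmsd$shifts), "\n")
  invisible(x)
}

#' @export
plot.fsc_curve <- function(x, threshold = c(0.5, 0.143), ...) {
  graphics::plot(x$shell_freqs, x$correlations, type = "l",
                 xlab = "spatial frequency (1/A)", ylab = "FSC",
                 ylim = c(min(0, min(x$correlations)), 1), ...)
  graphics::abline(h = threshold, lty = 3, col = "grey40")
  invisible(x)
}
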