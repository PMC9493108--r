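# Shared synthetic fixtures, built in code at load time.
#
# ref_model(): a 320-point asymmetric "fake protein" (smoothed random
# walk, rms radius 13 A).  Its size is chosen so that normal-mode
# amplitudes on the reference scale (|q| up to ~280) displace it by a
# few to ~15 A RMSD, matching the amplitude-to-RMSD ratio of a
# few-hundred-residue complex.
#
# helix_model(): a 48-point noisy helix, cheap and connected at an
# 8 A interaction radius (exactly 6 rigid-body modes).

make_random_walk_model <- function(n = 320, seed = 42,
                                   rms_radius = 13,
                                   gaussian_sigma = 1.5) {
  set.seed(seed)
  steps <- matrix(stats::rnorm(3 * (n + 30)), ncol = 3)
  steps <- apply(steps, 2, function(v)
    stats::filter(v, rep(1 / 15, 15), sides = 2))
  steps <- steps[stats::complete.cases(steps), ][seq_len(n), ]
  steps <- steps / sqrt(rowSums(steps^2)) * 1.1
  coords <- apply(steps, 2, cumsum)
  coords <- coords + matrix(stats::rnorm(3 * n, 0, 0.4), ncol = 3)
  coords <- sweep(coords, 2, colMeans(coords))
  coords <- coords * rms_radius / sqrt(mean(rowSums(coords^2)))
  coarse_model(coords, gaussian_sigma = gaussian_sigma)
}

make_helix_model <- function(n = 48, seed = 42, noise = 0.5) {
  set.seed(seed)
  t <- seq(0, 4 * pi, length.out = n)
  coords <- cbind(6 * cos(t), 6 * sin(t), 1.4 * t)
  coords <- coords + matrix(stats::rnorm(3 * n, 0, noise), ncol = 3)
  coarse_model(sweep(coords, 2, colMeans(coords)),
               gaussian_sigma = 1.5)
}

## memoized heavy fixtures (eigendecomposition done once per test run)
.fixture_env <- new.env(parent = emptyenv())

ref_model <- function() {
  if (is.null(.fixture_env$model))
    .fixture_env$model <- make_random_walk_model()
  .fixture_env$model
}

ref_modes <- function() {
  if (is.null(.fixture_env$modes)) {
    m <- ref_model()
    h <- build_enm_hessian(m, 8)
    .fixture_env$modes <- compute_modes(h, 3, interaction_radius = 8)
  }
  .fixture_env$modes
}

helix_model <- function() {
  if (is.null(.fixture_env$helix))
    .fixture_env$helix <- make_helix_model()
  .fixture_env$helix
}

helix_modes <- function(n_modes = 3) {
  key <- paste0("helix_modes_", n_modes)
  if (is.null(.fixture_env[[key]])) {
    h <- build_enm_hessian(helix_model(), 8)
    .fixture_env[[key]] <- compute_modes(h, n_modes,
                                         interaction_radius = 8)
  }
  .fixture_env[[key]]
}

## full-scale-like reference: 1600 points, 18 A rms radius, so the
## trajectory amplitude scale (|q| up to ~283) maps to 5-7 A RMSD --
## the same amplitude-to-deformation ratio as a full-atom model of a
## few-hundred-residue complex
big_model <- function() {
  if (is.null(.fixture_env$big))
    .fixture_env$big <- make_random_walk_model(n = 1600, seed = 42,
                                               rms_radius = 18)
  .fixture_env$big
}

big_modes <- function() {
  if (is.null(.fixture_env$big_modes)) {
    h <- build_enm_hessian(big_model(), 8)
    .fixture_env$big_modes <- compute_modes(h, 3,
                                            interaction_radius = 8)
  }
  .fixture_env$big_modes
}

## a 2-residue, 16-atom toy PDB written to a temp file
write_toy_pdb <- function(path = tempfile(fileext = ".pdb"),
                          hetatm_water_only = FALSE) {
  if (hetatm_water_only) {
    lines <- sprintf(
      "HETATM%5d  O   HOH A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      1:3, 1:3, runif(3, 0, 9), runif(3, 0, 9), runif(3, 0, 9))
  } else {
    names8 <- c("N", "CA", "C", "O", "CB", "CG", "CD", "CE")
    lines <- character(0)
    at <- 0
    for (res in 1:2) {
      for (nm in names8) {
        at <- at + 1
        lines <- c(lines, sprintf(
          "ATOM  %5d  %-3s ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          at, nm, res, at * 1.1, res * 2.0, at * 0.3))
      }
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

ncc_of <- function(a, b) stats::cor(as.numeric(a), as.numeric(b))

random_euler <- function(n) {
  cbind(stats::runif(n, 0, 360), stats::runif(n, 0, 180),
        stats::runif(n, 0, 360))
}
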