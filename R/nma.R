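## Elastic-network normal mode analysis.
##
## The ENM connects every pair of points closer than the interaction
## radius with a Hookean spring of uniform constant gamma = 1 (only the
## eigenvector directions matter downstream: normal-mode amplitudes are
## dimensionless by convention).  Modes are unit-norm over all 3N
## coordinates and not mass-weighted, which makes the amplitude <->
## RMSD relation exact: a single-mode displacement of amplitude q moves
## the model by RMSD |q| / sqrt(N).
##
## Coordinate flattening is interleaved: (x1, y1, z1, x2, ...), matching
## the 3x3 block layout of the Hessian.

#' Build the anisotropic elastic-network Hessian
#'
#' For each pair `i != j` with `|r_i - r_j| <= interaction_radius` the
#' off-diagonal 3x3 block is `-gamma * d d^T / |d|^2` with
#' `d = r_i - r_j` and `gamma = 1`; diagonal blocks are minus the row
#' sums of the off-diagonal blocks, so every block row sums to zero
#' (translation invariance).
#'
#' @param model A [coarse_model()].
#' @param interaction_radius Spring cutoff in Angstrom (> 0).
#' @return Symmetric 3N x 3N matrix.
#' @export
build_enm_hessian <- function(model, interaction_radius) {
  stopifnot(inherits(model, "coarse_model"))
  if (interaction_radius <= 0) stop("interaction_radius must be > 0")
  x <- model$coords
  n <- nrow(x)
  h <- matrix(0, 3L * n, 3L * n)
  d2 <- as.matrix(stats::dist(x))^2
  cutoff2 <- interaction_radius^2
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (d2[i, j] > cutoff2) next
      if (d2[i, j] == 0)
        stop(sprintf("points %d and %d coincide; spring direction undefined",
                     i, j))
      d <- x[i, ] - x[j, ]
      blk <- -tcrossprod(d) / d2[i, j]
      ri <- (3L * i - 2L):(3L * i)
      rj <- (3L * j - 2L):(3L * j)
      h[ri, rj] <- blk
      h[rj, ri] <- blk
      h[ri, ri] <- h[ri, ri] - blk
      h[rj, rj] <- h[rj, rj] - blk
    }
  }
  h
}

.normal_mode_set <- function(vectors, eigenvalues, interaction_radius,
                             source) {
  vectors <- as.matrix(vectors)
  nrm <- sqrt(colSums(vectors^2))
  vectors <- sweep(vectors, 2, nrm, "/")
  structure(list(vectors = vectors, eigenvalues = eigenvalues,
                 interaction_radius = interaction_radius,
                 source = source),
            class = "normal_mode_set")
}

#' @export
print.normal_mode_set <- function(x, ...) {
  cat(sprintf("normal_mode_set: %d modes over %d points (%s)\n",
              ncol(x$vectors), nrow(x$vectors) / 3L, x$source))
  cat("eigenvalues:", format(x$eigenvalues, digits = 4), "\n")
  invisible(x)
}

#' Per-point displacement field of one mode
#' @param modeset A `normal_mode_set`.
#' @param k Mode index within the set.
#' @return N x 3 matrix (unit norm over all 3N entries).
#' @export
mode_displacement <- function(modeset, k) {
  t(matrix(modeset$vectors[, k], nrow = 3L))
}

#' Diagonalize a Hessian into a normal mode set
#'
#' Dense symmetric eigendecomposition; eigenvalues ascend.  With
#' `skip_rigid` the six lowest (rigid-body) eigenpairs are discarded,
#' so the first returned flexible mode is conventionally "mode 7".
#'
#' @param hessian Symmetric 3N x 3N matrix.
#' @param n_modes Number of modes to return.
#' @param skip_rigid Discard the 6 rigid-body modes first (default
#'   TRUE).
#' @param interaction_radius Recorded in the result for provenance.
#' @return A `normal_mode_set` with fields `vectors` (3N x n_modes,
#'   unit columns), `eigenvalues` (ascending), `source`.
#' @export
compute_modes <- function(hessian, n_modes, skip_rigid = TRUE,
                          interaction_radius = NA_real_) {
  n3 <- nrow(hessian)
  skip <- if (skip_rigid) 6L else 0L
  if (n_modes > n3 - skip)
    stop(sprintf("requested %d modes but only %d are available",
                 n_modes, n3 - skip))
  e <- eigen(hessian, symmetric = TRUE)
  ord <- rev(seq_len(n3))               # ascending eigenvalues
  vals <- pmax(e$values[ord], 0)
  vecs <- e$vectors[, ord, drop = FALSE]
  idx <- (skip + 1L):(skip + n_modes)
  .normal_mode_set(vecs[, idx, drop = FALSE], vals[idx],
                   interaction_radius, "full-ENM")
}

## Orthonormal rigid-body basis (3 translations + 3 rotations about the
## centroid) for one block of points; degenerate directions dropped.
.rtb_block_basis <- function(coords) {
  n <- nrow(coords)
  ctr <- colMeans(coords)
  rel <- sweep(coords, 2, ctr)
  b <- matrix(0, 3L * n, 6L)
  for (a in 1:3) b[seq(a, 3L * n, by = 3L), a] <- 1
  for (i in seq_len(n)) {
    r <- rel[i, ]
    rows <- (3L * i - 2L):(3L * i)
    b[rows, 4L] <- c(0, r[3], -r[2])     # rotation about x
    b[rows, 5L] <- c(-r[3], 0, r[1])     # rotation about y
    b[rows, 6L] <- c(r[2], -r[1], 0)     # rotation about z
  }
  qr_b <- qr(b)
  qr.Q(qr_b)[, seq_len(qr_b$rank), drop = FALSE]
}

#' Rotation-translation-block (RTB) normal modes
#'
#' Consecutive residues are grouped into blocks of `block_size`
#' residues that may only translate and rotate rigidly.  The Hessian is
#' projected onto the per-block rigid-body basis (at most 6 B degrees
#' of freedom), diagonalized there, and eigenvectors are back-projected
#' to all-atom space and re-normalized.  RTB eigenvalues upper-bound
#' the corresponding full-ENM ones (Rayleigh-Ritz).
#'
#' @param model A [coarse_model()] whose labels carry `resno`.
#' @param hessian Full ENM Hessian of `model`.
#' @param block_size Residues per block (>= 1).
#' @param n_modes Flexible modes to return (after the 6 rigid ones).
#' @param interaction_radius Recorded for provenance.
#' @return A `normal_mode_set` with `source = "RTB(block_size)"`.
#' @export
compute_modes_rtb <- function(model, hessian, block_size, n_modes,
                              skip_rigid = TRUE,
                              interaction_radius = NA_real_) {
  stopifnot(inherits(model, "coarse_model"), block_size >= 1)
  resno <- model$labels$resno
  ures <- unique(resno)
  nblocks <- max(1L, ceiling(length(ures) / block_size))
  block_of_res <- rep(seq_len(nblocks),
                      each = block_size)[seq_along(ures)]
  block <- block_of_res[match(resno, ures)]
  ## blocks with no points cannot arise (blocks are defined from the
  ## residues present); a block with a single point still yields its
  ## translation basis after rank reduction
  basis <- vector("list", nblocks)
  n <- nrow(model$coords)
  p <- matrix(0, 3L * n, 0L)
  for (b in seq_len(nblocks)) {
    pts <- which(block == b)
    bb <- .rtb_block_basis(model$coords[pts, , drop = FALSE])
    cols <- matrix(0, 3L * n, ncol(bb))
    rows <- as.vector(rbind(3L * pts - 2L, 3L * pts - 1L, 3L * pts))
    cols[rows, ] <- bb
    p <- cbind(p, cols)
  }
  hp <- crossprod(p, hessian %*% p)
  hp <- (hp + t(hp)) / 2
  nb <- ncol(p)
  skip <- if (skip_rigid) 6L else 0L
  if (n_modes > nb - skip)
    stop(sprintf("RTB subspace has only %d flexible modes", nb - skip))
  e <- eigen(hp, symmetric = TRUE)
  ord <- rev(seq_len(nb))
  vals <- pmax(e$values[ord], 0)
  vecs <- p %*% e$vectors[, ord, drop = FALSE]
  idx <- (skip + 1L):(skip + n_modes)
  .normal_mode_set(vecs[, idx, drop = FALSE], vals[idx],
                   interaction_radius, sprintf("RTB(%d)", block_size))
}

#' Displace a model along a linear combination of modes
#'
#' `coords' = coords + sum_m q_m * mode_m`; labels, masses and sigma
#' are unchanged.  Because modes are unit-norm over 3N coordinates, the
#' total displacement norm equals `|q|` for a single mode and the RMSD
#' from the reference is `|q| / sqrt(N)`.
#'
#' @param model A [coarse_model()].
#' @param modeset A `normal_mode_set` for the same model.
#' @param amplitudes Numeric vector, one amplitude per mode in the set.
#' @return The displaced [coarse_model()].
#' @export
apply_amplitudes <- function(model, modeset, amplitudes) {
  stopifnot(inherits(model, "coarse_model"),
            inherits(modeset, "normal_mode_set"))
  if (length(amplitudes) != ncol(modeset$vectors))
    stop(sprintf("%d amplitudes for %d modes", length(amplitudes),
                 ncol(modeset$vectors)))
  disp <- modeset$vectors %*% amplitudes
  out <- model
  out$coords <- model$coords + t(matrix(disp, nrow = 3L))
  out
}

#' Represent a density map with pseudoatoms
#'
#' A deliberately simple density-weighted placement: above-threshold
#' voxel centers are partitioned by nearest-center assignment and each
#' center moves to the density-weighted centroid of its voxels
#' (Lloyd-style iterations, deterministic farthest-point
#' initialization).  The pseudoatom width is fixed at
#' `1.5 * voxel_size`.  The returned model carries attribute
#' `map_correlation`: the Pearson correlation between the input map and
#' the map rendered from the pseudoatoms.
#'
#' @param map A [density_map()].
#' @param n_points Number of pseudoatoms.
#' @param threshold Density threshold defining the support.
#' @param max_iter Lloyd iterations (default 30).
#' @return A [coarse_model()] of pseudoatoms (masses proportional to
#'   assigned density).
#' @export
pseudoatomize <- function(map, n_points, threshold, max_iter = 30L) {
  stopifnot(inherits(map, "density_map"))
  d <- dim(map$data)[1]
  sel <- which(map$data > threshold, arr.ind = TRUE)
  if (nrow(sel) == 0L)
    stop("threshold is above the map maximum: empty support")
  if (n_points > nrow(sel))
    stop(sprintf("n_points = %d exceeds the %d above-threshold voxels",
                 n_points, nrow(sel)))
  w <- map$data[sel]
  ## voxel (1-based index i) center in Angstrom: the model origin sits
  ## at grid index size/2 (0-based), matching render_density
  pts <- (sel - 1 - d / 2) * map$voxel_size
  pts <- sweep(pts, 2, map$origin, "+")
  ## deterministic farthest-point init from the densest voxel
  centers <- matrix(0, n_points, 3)
  centers[1, ] <- pts[which.max(w), ]
  if (n_points > 1L) {
    mind <- rowSums(sweep(pts, 2, centers[1, ])^2)
    for (k in 2:n_points) {
      centers[k, ] <- pts[which.max(mind * w), ]
      mind <- pmin(mind, rowSums(sweep(pts, 2, centers[k, ])^2))
    }
  }
  assign <- integer(nrow(pts))
  for (it in seq_len(max_iter)) {
    d2 <- outer(rowSums(pts^2), rowSums(centers^2), "+") -
      2 * pts %*% t(centers)
    new_assign <- max.col(-d2)
    if (identical(new_assign, assign)) break
    assign <- new_assign
    for (k in seq_len(n_points)) {
      in_k <- assign == k
      if (!any(in_k)) {                         # re-seed empty cluster
        far <- which.max(d2[cbind(seq_len(nrow(pts)), assign)])
        centers[k, ] <- pts[far, ]
        next
      }
      wk <- w[in_k]
      centers[k, ] <- colSums(pts[in_k, , drop = FALSE] * wk) / sum(wk)
    }
  }
  masses <- vapply(seq_len(n_points),
                   function(k) sum(w[assign == k]), numeric(1))
  masses[masses <= 0] <- min(w)
  model <- coarse_model(centers, masses = masses,
                        gaussian_sigma = 1.5 * map$voxel_size)
  rendered <- render_density(model, d, map$voxel_size,
                             origin = map$origin)
  attr(model, "map_correlation") <-
    stats::cor(as.numeric(rendered$data), as.numeric(map$data))
  model
}

#' Write / read a normal mode set as plain-text files
#'
#' Each mode becomes `mode_<k>.txt` (N rows, 3 columns of displacement)
#' in `dir`, plus `eigenvalues.txt` listing one eigenvalue per line and
#' an `index.txt` naming the files; interoperable and diffable.
#'
#' @param dir Directory (created if needed).
#' @param modeset A `normal_mode_set`.
#' @return `write_modes`: `dir`; `read_modes`: a `normal_mode_set`.
#' @export
write_modes <- function(dir, modeset) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- ncol(modeset$vectors)
  files <- sprintf("mode_%03d.txt", seq_len(m))
  for (k in seq_len(m))
    utils::write.table(mode_displacement(modeset, k),
                       file.path(dir, files[k]),
                       row.names = FALSE, col.names = FALSE)
  writeLines(format(modeset$eigenvalues, digits = 17),
             file.path(dir, "eigenvalues.txt"))
  writeLines(files, file.path(dir, "index.txt"))
  invisible(dir)
}

#' @rdname write_modes
#' @export
read_modes <- function(dir) {
  files <- readLines(file.path(dir, "index.txt"))
  vals <- as.numeric(readLines(file.path(dir, "eigenvalues.txt")))
  vecs <- vapply(files, function(f) {
    m <- as.matrix(utils::read.table(file.path(dir, f)))
    as.numeric(t(m))
  }, numeric(3L * nrow(utils::read.table(file.path(dir, files[1])))))
  dimnames(vecs) <- NULL
  .normal_mode_set(vecs, vals, NA_real_, "file")
}
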