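## Rotation representations and the angular metric used throughout the
## pipeline.  Convention (fixed once, used identically by the simulator,
## the aligner and the reconstructor):
##   R = Rz(rot) %*% Ry(tilt) %*% Rz(psi), angles in degrees,
## each factor a right-handed rotation about the named *fixed* axis.
## Quaternions are (w, x, y, z), unit norm, canonical sign w >= 0 (ties
## broken by the first nonzero component being positive).

.deg2rad <- pi / 180
.rad2deg <- 180 / pi

rot_z <- function(a) {
  a <- a * .deg2rad
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}

rot_y <- function(a) {
  a <- a * .deg2rad
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3)
}

#' Convert ZYZ Euler angles to a rotation matrix
#'
#' Angles follow the ZYZ convention used across the whole pipeline:
#' `R = Rz(rot) Ry(tilt) Rz(psi)` with right-handed rotations about the
#' fixed z, y and z axes, in degrees.
#'
#' @param rot,tilt,psi Euler angles in degrees.
#' @return A 3x3 rotation matrix.
#' @export
euler_to_rotation <- function(rot, tilt, psi) {
  rot_z(rot) %*% rot_y(tilt) %*% rot_z(psi)
}

#' Recover ZYZ Euler angles from a rotation matrix
#'
#' At gimbal lock (tilt near 0 or 180 degrees) `psi` is set to 0 and the
#' in-plane rotation folded into `rot`.
#'
#' @param R 3x3 rotation matrix.
#' @return Named numeric vector `c(rot, tilt, psi)` in degrees, with
#'   `rot, psi` wrapped to `[0, 360)` and `tilt` to `[0, 180]`.
#' @export
rotation_to_euler <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3L, 3L)))
  ct <- max(-1, min(1, R[3, 3]))
  tilt <- acos(ct) * .rad2deg
  if (abs(ct) > 1 - 1e-12) {
    ## tilt ~ 0 or 180: rot and psi degenerate; fold into rot
    if (ct > 0) {
      rot <- atan2(R[2, 1], R[1, 1]) * .rad2deg
    } else {
      rot <- atan2(-R[2, 1], -R[1, 1]) * .rad2deg
    }
    psi <- 0
  } else {
    rot <- atan2(R[2, 3], R[1, 3]) * .rad2deg
    psi <- atan2(R[3, 2], -R[3, 1]) * .rad2deg
  }
  c(rot = rot %% 360, tilt = tilt, psi = psi %% 360)
}

#' Canonicalize a quaternion's sign
#'
#' The double cover of SO(3) maps q and -q to the same rotation; the
#' canonical representative has `w >= 0`, ties broken by the first
#' nonzero component being positive.
#'
#' @param q Length-4 numeric `(w, x, y, z)`.
#' @return The canonical-sign quaternion (not re-normalized).
#' @export
quaternion_canonicalize <- function(q) {
  stopifnot(length(q) == 4L)
  nz <- which(abs(q) > 0)
  if (length(nz) == 0L) stop("zero quaternion has no canonical form")
  if (q[nz[1L]] < 0) q <- -q
  q
}

#' @rdname rotation_to_quaternion
#' @param q Length-4 unit quaternion `(w, x, y, z)`; normalized defensively.
#' @export
quaternion_to_rotation <- function(q) {
  stopifnot(length(q) == 4L)
  n <- sqrt(sum(q^2))
  if (n < 1e-12) stop("zero quaternion is not a rotation")
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z),     2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2),     2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x),     1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

#' Convert between rotation matrices and unit quaternions
#'
#' Shepperd's numerically stable branch selection; the returned
#' quaternion carries the canonical sign (`w >= 0`).
#'
#' @param R 3x3 rotation matrix.
#' @return `rotation_to_quaternion`: length-4 `(w, x, y, z)` unit
#'   quaternion; `quaternion_to_rotation`: 3x3 rotation matrix.
#' @export
rotation_to_quaternion <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3L, 3L)))
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s,
           0.25 * s,
           (R[2, 1] + R[1, 2]) / s,
           (R[3, 1] + R[1, 3]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 - R[1, 1] + R[2, 2] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s,
           (R[2, 1] + R[1, 2]) / s,
           0.25 * s,
           (R[3, 2] + R[2, 3]) / s)
  } else {
    s <- sqrt(1 - R[1, 1] - R[2, 2] + R[3, 3]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s,
           (R[3, 1] + R[1, 3]) / s,
           (R[3, 2] + R[2, 3]) / s,
           0.25 * s)
  }
  quaternion_canonicalize(q / sqrt(sum(q^2)))
}

#' @rdname euler_quaternion
#' @export
euler_to_quaternion <- function(rot, tilt, psi) {
  rotation_to_quaternion(euler_to_rotation(rot, tilt, psi))
}

#' Convert between ZYZ Euler angles and quaternions
#'
#' Convenience compositions of the matrix conversions; quaternions are
#' canonical-sign, Euler angles follow the package's ZYZ convention.
#'
#' @param rot,tilt,psi Euler angles in degrees.
#' @param q Length-4 unit quaternion.
#' @name euler_quaternion
#' @export
quaternion_to_euler <- function(q) {
  rotation_to_euler(quaternion_to_rotation(q))
}

#' Axis-based angular distance between two rotations
#'
#' The mean, over the three coordinate axes, of the angle between the
#' images of that axis under the two rotations:
#' `mean_k arccos(<R1 e_k, R2 e_k>)`, in degrees.  Symmetric, zero iff
#' the rotations are equal.  This is the orientation-error metric used
#' in all evaluation reports.
#'
#' @param R1,R2 3x3 rotation matrices.
#' @return Angular distance in degrees.
#' @export
angular_distance <- function(R1, R2) {
  ## arccos of the per-axis dot product, evaluated through the chord
  ## length 2 asin(|a - b| / 2) for full precision at small angles
  chord <- sqrt(colSums((R1 - R2)^2))
  mean(2 * asin(pmin(1, chord / 2))) * .rad2deg
}

#' Geodesic (axis-angle) distance between two rotations
#'
#' The rotation angle of `R1^T R2`, in degrees.  Provided for
#' diagnostics; evaluation reports use [angular_distance()].
#'
#' @inheritParams angular_distance
#' @return Geodesic angle in degrees.
#' @export
geodesic_distance <- function(R1, R2) {
  tr <- sum(diag(crossprod(R1, R2)))
  acos(pmax(-1, pmin(1, (tr - 1) / 2))) * .rad2deg
}
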