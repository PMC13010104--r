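#' Rotation matrix from intrinsic ZYX Euler angles
#'
#' Builds `R = Rz(ez) %*% Ry(ey) %*% Rx(ex)` (intrinsic Z-Y-X sequence).
#' Columns of the result are the local frame axes expressed in global
#' coordinates; for a cross-section the local x axis is the ellipse-plane
#' normal (backbone tangent), local y the lateral in-plane axis and local z
#' the dorsal in-plane axis.
#'
#' @param euler_zyx numeric length-3 `(ez, ey, ex)` in radians.
#' @return 3x3 orthonormal matrix.
#' @export
euler_zyx_to_matrix <- function(euler_zyx) {
  stopifnot(length(euler_zyx) == 3, all(is.finite(euler_zyx)))
  cz <- cos(euler_zyx[1]); sz <- sin(euler_zyx[1])
  cy <- cos(euler_zyx[2]); sy <- sin(euler_zyx[2])
  cx <- cos(euler_zyx[3]); sx <- sin(euler_zyx[3])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Rz %*% Ry %*% Rx
}

#' ZYX Euler angles of a rotation matrix
#'
#' Inverse of [euler_zyx_to_matrix()]. At the gimbal singularity
#' (`|R[3,1]| = 1`) the x angle is set to zero.
#'
#' @param R 3x3 rotation matrix.
#' @return numeric `(ez, ey, ex)` in radians.
#' @export
matrix_to_euler_zyx <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)))
  sy <- -R[3, 1]
  sy <- max(-1, min(1, sy))
  ey <- asin(sy)
  if (abs(sy) < 1 - 1e-12) {
    ez <- atan2(R[2, 1], R[1, 1])
    ex <- atan2(R[3, 2], R[3, 3])
  } else {
    ez <- atan2(-R[1, 2], R[2, 2])
    ex <- 0
  }
  c(ez, ey, ex)
}

# Rotation matrix about a unit axis by angle (radians), Rodrigues form.
rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Axis-angle (rotation) vector of a rotation matrix: axis * angle, radians.
# Continuous at the identity; handles angles near pi via the diagonal.
rotation_vector <- function(R) {
  tr <- sum(diag(R))
  cang <- max(-1, min(1, (tr - 1) / 2))
  angle <- acos(cang)
  if (angle < 1e-12) return(c(0, 0, 0))
  w <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (angle < pi - 1e-6) {
    return(w * angle / (2 * sin(angle)))
  }
  # near pi: extract axis from R + I
  B <- (R + diag(3)) / 2
  axis <- sqrt(pmax(diag(B), 0))
  # fix signs using the off-diagonal terms
  i <- which.max(axis)
  if (axis[i] > 0) {
    axis <- B[, i] / axis[i]
    axis <- axis / sqrt(sum(axis^2))
  }
  if (sum(w * axis) < 0) axis <- -axis
  axis * angle
}
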