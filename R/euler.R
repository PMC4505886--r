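## Euler-angle conventions.
##
## "xyz order" here means intrinsic rotations about x, then y, then z, i.e.
## the extrinsic matrix product R = Rz(theta) %*% Ry(psi) %*% Rx(phi).
## Externally everything is degrees; radians appear only inside this file.
## Test vectors: (90, 0, 0) maps e_y -> e_z; (0, 90, 0) maps e_z -> e_x;
## (0, 0, 90) maps e_x -> e_y.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles into (-180, 180] degrees
#'
#' @param x Numeric vector of angles in degrees.
#' @return Angles wrapped componentwise into the half-open interval
#'   `(-180, 180]`.
#' @export
wrap_angle <- function(x) {
  w <- ((x + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}

#' Rotation matrix from xyz-order Euler angles
#'
#' Composes `Rz(theta) Ry(psi) Rx(phi)` (intrinsic x-y-z order).
#'
#' @param phi,psi,theta Angles in degrees (rotation about x, y, z). A single
#'   length-3 vector `c(phi, psi, theta)` may be given as `phi`.
#' @return 3x3 proper rotation matrix.
#' @seealso [euler_xyz_from_rotation()]
#' @export
rotation_from_euler_xyz <- function(phi, psi = NULL, theta = NULL) {
  if (is.null(psi) && length(phi) == 3) {
    psi <- phi[2]; theta <- phi[3]; phi <- phi[1]
  }
  a <- deg2rad(phi); b <- deg2rad(psi); c <- deg2rad(theta)
  Rx <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  Rz <- matrix(c(cos(c), sin(c), 0, -sin(c), cos(c), 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' xyz-order Euler angles of a rotation matrix
#'
#' Decomposes a proper rotation into the triple (phi, psi, theta) such that
#' [rotation_from_euler_xyz()] reproduces the input. At gimbal lock
#' (`|psi| = 90` degrees) the split between phi and theta is undefined; the
#' convention `phi := 0` is applied.
#'
#' @param R 3x3 proper rotation matrix.
#' @param tol Orthonormality tolerance for input validation.
#' @return Named numeric vector `c(phi, psi, theta)` in degrees, each
#'   component in `(-180, 180]`.
#' @examples
#' euler_xyz_from_rotation(rotation_from_euler_xyz(10, -20, 30))
#' @export
euler_xyz_from_rotation <- function(R, tol = 1e-6) {
  R <- as.matrix(R)
  if (!is_rotation_matrix(R, tol = tol))
    stop("input is not a proper rotation matrix (orthonormal, det +1)")
  s <- -R[3, 1]
  if (abs(s) >= 1 - 1e-12) {
    psi <- if (s > 0) pi / 2 else -pi / 2
    phi <- 0
    theta <- atan2(-R[1, 2], R[2, 2])
  } else {
    psi <- asin(s)
    phi <- atan2(R[3, 2], R[3, 3])
    theta <- atan2(R[2, 1], R[1, 1])
  }
  out <- wrap_angle(rad2deg(c(phi, psi, theta)))
  names(out) <- c("phi", "psi", "theta")
  out
}

#' Euler-angle distance (EAD) between two orientations
#'
#' The Euclidean norm of the componentwise Euler-angle differences,
#' `sqrt(dphi^2 + dpsi^2 + dtheta^2)`, with each difference wrapped into
#' `(-180, 180]` degrees first. This is the similarity measure used for all
#' geometry comparisons and clustering.
#'
#' @param a,b Euler triples `c(phi, psi, theta)` in degrees.
#' @return Distance in degrees (non-negative scalar).
#' @examples
#' euler_angle_distance(c(3, 4, 0), c(0, 0, 0))  # 5
#' @export
euler_angle_distance <- function(a, b) {
  stopifnot(length(a) == 3, length(b) == 3, all(is.finite(c(a, b))))
  sqrt(sum(wrap_angle(as.numeric(a) - as.numeric(b))^2))
}
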