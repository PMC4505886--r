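#' Rigid-body transform
#'
#' A proper rigid transform `x -> R x + t` used for every superposition and
#' cuboid pose in the package.
#'
#' @param rotation 3x3 proper rotation matrix (orthonormal, det +1).
#' @param translation length-3 numeric translation, in Angstrom.
#' @return An object of class `rigid_transform` with elements `rotation`
#'   and `translation`.
#' @examples
#' tr <- rigid_transform(diag(3), c(1, 0, 0))
#' apply_transform(tr, matrix(0, 1, 3))
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(identical(dim(rotation), c(3L, 3L)), length(translation) == 3)
  if (!is_rotation_matrix(rotation, tol = 1e-9))
    stop("'rotation' must be orthonormal with determinant +1 (tol 1e-9)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

is_rotation_matrix <- function(R, tol = 1e-6) {
  is.matrix(R) && all(dim(R) == 3) && all(is.finite(R)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

#' Apply a rigid transform to coordinates
#'
#' @param transform A [rigid_transform()].
#' @param xyz Numeric n x 3 coordinate matrix (or a length-3 vector).
#' @return Transformed coordinates, same shape as `xyz`.
#' @export
apply_transform <- function(transform, xyz) {
  stopifnot(inherits(transform, "rigid_transform"))
  vec <- is.null(dim(xyz))
  if (vec) xyz <- matrix(xyz, 1, 3)
  out <- xyz %*% t(transform$rotation) +
    rep(transform$translation, each = nrow(xyz))
  if (vec) drop(out) else out
}

#' Invert a rigid transform
#'
#' @param transform A [rigid_transform()].
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -drop(Rt %*% transform$translation))
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` is the transform equivalent to applying `b`
#' first, then `a`.
#'
#' @param a,b [rigid_transform()] objects.
#' @return A `rigid_transform`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  drop(a$rotation %*% b$translation) + a$translation)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rigid transform minimising the summed squared distance
#' `sum || R p_i + t - q_i ||^2` between paired points, via SVD of the
#' cross-covariance with the standard reflection correction.
#'
#' @param P,Q n x 3 matrices of paired coordinates (`P` is moved onto `Q`).
#' @param weights Optional non-negative per-pair weights.
#' @return A list with `transform` (a [rigid_transform()]) and `rmsd`, the
#'   root-mean-square residual of the matched pairs after superposition.
#' @export
kabsch <- function(P, Q, weights = NULL) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  stopifnot(ncol(P) == 3, ncol(Q) == 3, nrow(P) == nrow(Q), nrow(P) >= 3)
  n <- nrow(P)
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)
  stopifnot(length(w) == n, all(w >= 0), sum(w) > 0)
  w <- w / sum(w)
  pc <- colSums(P * w); qc <- colSums(Q * w)
  Pc <- sweep(P, 2, pc); Qc <- sweep(Q, 2, qc)
  H <- crossprod(Pc * w, Qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- qc - drop(R %*% pc)
  res <- Pc %*% t(R) - Qc
  rmsd <- sqrt(mean(rowSums(res^2)))
  list(transform = rigid_transform(R, t), rmsd = rmsd)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform\n  rotation:\n")
  print(round(x$rotation, 6))
  cat("  translation:", paste(round(x$translation, 4), collapse = ", "), "\n")
  invisible(x)
}
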