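## Cuboid frames.
##
## Each variable domain carries a rigid rectangular box (cuboid) whose axes
## are the principal axes of the framework-anchor C-alphas and whose extents
## cover the domain's atoms. The cuboid gives every domain a unified local
## frame, so the pose of a beta domain relative to the reference structure
## is a single rigid transform whose rotation is summarised by one Euler
## triple.

#' Cuboid frame
#'
#' @param center Cuboid center, length-3, Angstrom.
#' @param half_extents Positive half-widths along the cuboid axes, Angstrom.
#' @param axes 3x3 proper rotation; columns are the cuboid axes expressed in
#'   reference coordinates.
#' @return Object of class `cuboid`.
#' @export
cuboid <- function(center, half_extents, axes) {
  center <- as.numeric(center); half_extents <- as.numeric(half_extents)
  axes <- as.matrix(axes)
  stopifnot(length(center) == 3, length(half_extents) == 3)
  if (any(half_extents <= 0)) stop("cuboid half_extents must be positive")
  if (!is_rotation_matrix(axes, tol = 1e-6))
    stop("cuboid axes must form a proper rotation matrix")
  structure(list(center = center, half_extents = half_extents, axes = axes),
            class = "cuboid")
}

#' @export
print.cuboid <- function(x, ...) {
  cat("Cuboid: center (", paste(round(x$center, 3), collapse = ", "),
      "), half extents (", paste(round(x$half_extents, 3), collapse = ", "),
      ") A\n", sep = "")
  invisible(x)
}

#' Build the reference cuboid of a domain
#'
#' Axes are the principal axes (eigenvectors of the covariance, decreasing
#' eigenvalue) of the template-anchor C-alpha coordinates. Eigenvector sign
#' ambiguity is removed by orienting the first two axes so their dot product
#' with the reference axis of the same rank is positive; the third axis is
#' their cross product, guaranteeing a right-handed frame. Extents are the
#' half-widths of the domain's atoms projected onto the axes; the center is
#' the projection midpoint, so the box covers the whole domain.
#'
#' @param domain The reference `variable_domain` (its atoms set the box
#'   size).
#' @param template The domain's [framework_template()] (its anchors set the
#'   axes).
#' @return A [cuboid()].
#' @export
build_reference_cuboid <- function(domain, template) {
  stopifnot(inherits(domain, "variable_domain"),
            inherits(template, "framework_template"))
  A <- template$anchor_coordinates
  if (nrow(A) < 3) stop("degenerate anchor set: fewer than 3 anchors")
  Ac <- sweep(A, 2, colMeans(A))
  ev <- eigen(crossprod(Ac) / nrow(Ac), symmetric = TRUE)
  if (ev$values[2] <= max(ev$values[1], 1) * 1e-10)
    stop("degenerate (collinear) anchors: principal axes undefined")
  axes <- ev$vectors
  for (k in 1:2) if (axes[k, k] < 0) axes[, k] <- -axes[, k]
  axes[, 3] <- c(axes[2, 1] * axes[3, 2] - axes[3, 1] * axes[2, 2],
                 axes[3, 1] * axes[1, 2] - axes[1, 1] * axes[3, 2],
                 axes[1, 1] * axes[2, 2] - axes[2, 1] * axes[1, 2])
  xyz <- as.matrix(domain$atoms[, c("x", "y", "z")])
  proj <- sweep(xyz, 2, colMeans(A)) %*% axes
  lo <- apply(proj, 2, min); hi <- apply(proj, 2, max)
  center <- colMeans(A) + drop(axes %*% ((lo + hi) / 2))
  cuboid(center, (hi - lo) / 2, axes)
}

#' Place the beta cuboid of an aligned complex
#'
#' For a complex already aligned on its alpha domain, computes the rigid
#' transform that maps the beta template anchors onto the structure's beta
#' anchors and applies it to the reference beta cuboid. The transform is the
#' beta-domain pose relative to the reference structure; its rotation is
#' what the Euler triples summarise.
#'
#' @param aligned An alpha-aligned `tcr_complex`.
#' @param beta_template Beta-chain [framework_template()] in the reference
#'   frame.
#' @param ref_cuboid Reference beta [cuboid()].
#' @return The placed [cuboid()] with attributes `pose`
#'   ([rigid_transform()]) and `rmsd` (beta anchor superposition residual).
#' @export
place_beta_cuboid <- function(aligned, beta_template, ref_cuboid) {
  pose <- beta_pose(aligned, beta_template)
  out <- cuboid(apply_transform(pose, ref_cuboid$center),
                ref_cuboid$half_extents,
                pose$rotation %*% ref_cuboid$axes)
  attr(out, "pose") <- pose
  attr(out, "rmsd") <- attr(pose, "rmsd")
  out
}

#' Beta-domain pose of an aligned complex
#'
#' The rigid transform carrying the reference beta anchors onto the aligned
#' structure's beta anchors (the inverse of superposing the structure's beta
#' domain onto the beta template).
#'
#' @inheritParams place_beta_cuboid
#' @return A [rigid_transform()] with attribute `rmsd`.
#' @export
beta_pose <- function(aligned, beta_template) {
  cx <- if (is.list(aligned) && !inherits(aligned, "tcr_complex"))
    aligned$complex else aligned
  stopifnot(inherits(cx, "tcr_complex"),
            beta_template$chain_type == "beta")
  sup <- superpose_on_template(cx$beta, beta_template)
  pose <- invert_transform(sup$transform)
  attr(pose, "rmsd") <- sup$rmsd
  pose
}

#' Beta-domain Euler triple of an aligned complex
#'
#' @inheritParams place_beta_cuboid
#' @return Named Euler triple `c(phi, psi, theta)` in degrees.
#' @export
beta_euler <- function(aligned, beta_template) {
  euler_xyz_from_rotation(beta_pose(aligned, beta_template)$rotation)
}
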