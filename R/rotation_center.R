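## Center-of-rotation search.
##
## A cubic grid is fit into the reference beta cuboid and carried along with
## every structure's beta pose; grid points are indexed identically across
## structures. For each grid index the variance of the pairwise distances
## between equivalent points is computed across the ensemble; the index
## minimising that variance is the common center of rotation (CoR): a point
## the ensemble of rigid poses moves least relative to itself.

#' Cubic grid in the reference frame
#'
#' The grid is centered on the cuboid center with axes parallel to the
#' reference axes; `extent` is the edge length so each axis carries
#' `extent / spacing + 1` points. Indexing is 1-based and x-fastest
#' (column-major over x, y, z), identical for every structure.
#'
#' @param cuboid A [cuboid()] (its center positions the grid) or a length-3
#'   center vector.
#' @param spacing Grid spacing in Angstrom (> 0, must divide `extent`).
#' @param extent Grid edge length in Angstrom.
#' @return Object of class `cor_grid` with `origin`, `spacing`,
#'   `points_per_axis`, `extent`, `center`.
#' @examples
#' g <- fit_grid(c(0, 0, 0), spacing = 1, extent = 2)
#' grid_point_count(g)  # 27
#' @export
fit_grid <- function(cuboid, spacing, extent) {
  center <- if (inherits(cuboid, "cuboid")) cuboid$center
            else as.numeric(cuboid)
  stopifnot(length(center) == 3)
  if (!is.numeric(spacing) || length(spacing) != 1 || spacing <= 0)
    stop("spacing must be a positive number")
  if (!is.numeric(extent) || length(extent) != 1 || extent <= 0)
    stop("extent must be a positive number")
  steps <- extent / spacing
  if (abs(steps - round(steps)) > 1e-9)
    stop("spacing (", spacing, " A) does not divide extent (", extent,
         " A)")
  npa <- as.integer(round(steps)) + 1L
  structure(list(origin = center - extent / 2, spacing = spacing,
                 points_per_axis = npa, extent = extent, center = center),
            class = "cor_grid")
}

#' Total number of grid points
#'
#' @param grid A [fit_grid()] object.
#' @return `points_per_axis ^ 3` (as a double: counts exceed the integer
#'   range for fine grids).
#' @export
grid_point_count <- function(grid) {
  stopifnot(inherits(grid, "cor_grid"))
  as.numeric(grid$points_per_axis)^3
}

#' Reference coordinates of grid points
#'
#' @param grid A [fit_grid()] object.
#' @param idx Optional 1-based point indices (x-fastest order); default all
#'   points (only sensible for coarse grids).
#' @return m x 3 coordinate matrix.
#' @export
grid_points <- function(grid, idx = NULL) {
  stopifnot(inherits(grid, "cor_grid"))
  npa <- grid$points_per_axis
  if (is.null(idx)) {
    total <- grid_point_count(grid)
    if (total > 2^24)
      stop("refusing to materialise ", format(total, big.mark = ","),
           " grid points; pass explicit indices")
    idx <- seq_len(total)
  }
  i0 <- idx - 1
  ix <- i0 %% npa
  iy <- (i0 %/% npa) %% npa
  iz <- i0 %/% (as.numeric(npa)^2)
  cbind(grid$origin[1] + ix * grid$spacing,
        grid$origin[2] + iy * grid$spacing,
        grid$origin[3] + iz * grid$spacing)
}

#' Transform grid points by a structure's pose
#'
#' @param points m x 3 reference grid-point coordinates (or a `cor_grid`,
#'   which is materialised first).
#' @param pose The structure's beta-cuboid pose ([rigid_transform()]).
#' @return m x 3 matrix of the points carried along with the structure.
#' @export
transform_grid_points <- function(points, pose) {
  if (inherits(points, "cor_grid")) points <- grid_points(points)
  apply_transform(pose, points)
}

#' Positional variance field over an ensemble of poses
#'
#' For every grid index `i`, computes the variance of the pairwise
#' Euclidean distances between the equivalent points of all structures:
#' over all `n^2` ordered structure pairs (including the zero self-pairs;
#' see `exclude_self`), with squared deviations from the pair mean and
#' `1 / (n^2 - 1)` normalisation.
#'
#' @param positions Either a list of n m x 3 matrices (the per-structure
#'   grid-point positions, identical shape) or an m x 3 matrix of reference
#'   points together with `poses`.
#' @param poses Optional list of n [rigid_transform()] poses applied to the
#'   reference `positions`.
#' @param exclude_self If `TRUE`, the n zero-distance self-pairs are left
#'   out (normalisation `1 / (n^2 - n - 1)`); the default `FALSE` matches
#'   the double sums as printed.
#' @return Object of class `variance_field`: list with `var` (length-m,
#'   Angstrom^2), `n` (structures), `exclude_self`.
#' @export
variance_field <- function(positions, poses = NULL, exclude_self = FALSE) {
  if (!is.null(poses)) {
    stopifnot(is.matrix(positions))
    positions <- lapply(poses, function(p) apply_transform(p, positions))
  }
  stopifnot(is.list(positions), length(positions) >= 2)
  dims <- lapply(positions, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
    stop("mismatched grid shapes across structures")
  n <- length(positions)
  m <- nrow(positions[[1]])
  sum_d <- numeric(m)
  sum_d2 <- numeric(m)
  for (k in seq_len(n - 1)) {
    for (l in (k + 1):n) {
      d2 <- rowSums((positions[[k]] - positions[[l]])^2)
      d <- sqrt(d2)
      sum_d <- sum_d + 2 * d       # ordered pairs (k,l) and (l,k)
      sum_d2 <- sum_d2 + 2 * d2
    }
  }
  n_pairs <- if (exclude_self) n^2 - n else n^2
  denom <- n_pairs - 1
  mu <- sum_d / n_pairs
  v <- (sum_d2 - n_pairs * mu^2) / denom
  v[v < 0] <- 0   # guard tiny negative round-off
  structure(list(var = v, n = n, exclude_self = exclude_self),
            class = "variance_field")
}

#' Locate the center of rotation in a variance field
#'
#' The CoR grid index is the argmin of the positional variance; ties are
#' broken to the lowest index. An ensemble with no rotational diversity
#' (field numerically zero everywhere) has no defined CoR.
#'
#' @param field A [variance_field()].
#' @param grid The [fit_grid()] the field was evaluated on (or an m x 3
#'   matrix of the evaluated point coordinates).
#' @param subset_used Label recorded in the result (`"all"`, `"bound"`,
#'   `"unbound"`).
#' @param degenerate_tol Field maximum (Angstrom^2) below which the
#'   ensemble is considered rotation-free.
#' @return Object of class `cor_result`: `i_min`, `coordinate` (reference
#'   frame, Angstrom), `variance_at_min`, `subset_used`, `n`.
#' @export
locate_cor <- function(field, grid, subset_used = "all",
                       degenerate_tol = 1e-12) {
  stopifnot(inherits(field, "variance_field"))
  v <- field$var
  if (max(v) < degenerate_tol)
    stop("degenerate CoR: ensemble has no rotational diversity ",
         "(variance field is zero everywhere)")
  i_min <- which.min(v)   # which.min returns the first (lowest) index
  coord <- if (inherits(grid, "cor_grid")) drop(grid_points(grid, i_min))
           else as.numeric(grid[i_min, ])
  structure(list(i_min = i_min, coordinate = coord,
                 variance_at_min = v[i_min], subset_used = subset_used,
                 n = field$n),
            class = "cor_result")
}

#' @export
print.cor_result <- function(x, ...) {
  cat("Center of rotation (", x$subset_used, ", n = ", x$n, "): index ",
      x$i_min, ", (", paste(sprintf("%.3f", x$coordinate), collapse = ", "),
      ") A, var ", format(x$variance_at_min, digits = 4), " A^2\n",
      sep = "")
  invisible(x)
}

#' Grid search for the common center of rotation
#'
#' Evaluates the variance field over a cubic grid and returns the argmin.
#' The default `"coarse2fine"` strategy runs a coarse pass
#' (`coarse_spacing`) over the full extent, then refines at `spacing`
#' inside a `refine_box` Angstrom box around the coarse minimum; an
#' `"exhaustive"` pass evaluates every point of the full-resolution grid in
#' memory-bounded chunks.
#'
#' @param poses List of beta-cuboid poses ([rigid_transform()]), one per
#'   structure.
#' @param cuboid Reference beta [cuboid()] (or center vector) the grid is
#'   fit into.
#' @param spacing Final grid spacing (Angstrom), default 0.1.
#' @param extent Grid edge length (Angstrom), default 32.
#' @param strategy `"coarse2fine"` or `"exhaustive"`.
#' @param coarse_spacing Spacing of the coarse pass (Angstrom), default 1.
#' @param refine_box Edge length of the refinement box (Angstrom).
#' @param subset_used Subset label recorded in the result.
#' @param chunk_size Points per chunk in exhaustive mode.
#' @return A `cor_result` (see [locate_cor()]) with attribute `field` (the
#'   final-pass [variance_field()]) and `grid` (the final-pass grid points
#'   evaluated).
#' @export
cor_search <- function(poses, cuboid, spacing = 0.1, extent = 32,
                       strategy = c("coarse2fine", "exhaustive"),
                       coarse_spacing = 1.0, refine_box = 3,
                       subset_used = "all", chunk_size = 262144L) {
  strategy <- match.arg(strategy)
  stopifnot(length(poses) >= 2)
  if (strategy == "coarse2fine") {
    coarse <- fit_grid(cuboid, coarse_spacing, extent)
    pts <- grid_points(coarse)
    f <- variance_field(pts, poses = poses)
    cres <- locate_cor(f, coarse, subset_used = subset_used)
    if (spacing >= coarse_spacing) {
      attr(cres, "field") <- f
      attr(cres, "grid") <- pts
      return(cres)
    }
    fine <- fit_grid(cres$coordinate, spacing, refine_box)
    fpts <- grid_points(fine)
    ff <- variance_field(fpts, poses = poses)
    res <- locate_cor(ff, fine, subset_used = subset_used)
    attr(res, "field") <- ff
    attr(res, "grid") <- fpts
    res
  } else {
    grid <- fit_grid(cuboid, spacing, extent)
    total <- grid_point_count(grid)
    best_v <- Inf; best_i <- NA_real_; max_v <- 0
    start <- 1
    while (start <= total) {
      idx <- seq(start, min(start + chunk_size - 1, total))
      pts <- grid_points(grid, idx)
      f <- variance_field(pts, poses = poses)
      j <- which.min(f$var)
      if (f$var[j] < best_v) { best_v <- f$var[j]; best_i <- idx[j] }
      max_v <- max(max_v, f$var)
      start <- start + chunk_size
    }
    if (is.na(best_i) || max_v < 1e-12)
      stop("degenerate CoR: ensemble has no rotational diversity ",
           "(variance field is zero everywhere)")
    structure(list(i_min = best_i,
                   coordinate = drop(grid_points(grid, best_i)),
                   variance_at_min = best_v, subset_used = subset_used,
                   n = length(poses)),
              class = "cor_result")
  }
}

#' Variance field as a coordinate table
#'
#' @param x A [variance_field()].
#' @param points The m x 3 coordinates the field was evaluated at.
#' @param ... Unused.
#' @return data.frame with `index`, `x`, `y`, `z`, `var`.
#' @export
as.data.frame.variance_field <- function(x, points, ...) {
  data.frame(index = seq_along(x$var), x = points[, 1], y = points[, 2],
             z = points[, 3], var = x$var)
}

#' Residue environment of a point
#'
#' All residues of the complex's alpha and beta domains with any atom
#' within `radius` of `point`, sorted by closest-atom distance.
#'
#' @param cx An (aligned) `tcr_complex`.
#' @param point Length-3 coordinate in the same frame, Angstrom.
#' @param radius Inclusion radius, Angstrom.
#' @return data.frame `chain_type`, `position`, `residue_name`, `min_dist`,
#'   sorted by `min_dist` (possibly zero rows).
#' @export
cor_environment <- function(cx, point, radius = 8) {
  stopifnot(inherits(cx, "tcr_complex"), length(point) == 3, radius >= 0)
  one <- function(domain) {
    a <- domain$atoms
    d <- sqrt((a$x - point[1])^2 + (a$y - point[2])^2 + (a$z - point[3])^2)
    key <- paste0(a$residue_number, a$insert)
    md <- tapply(d, key, min)
    rn <- tapply(a$residue_name, key, `[`, 1)
    data.frame(chain_type = domain$chain_type, position = names(md),
               residue_name = as.character(rn), min_dist = as.numeric(md),
               stringsAsFactors = FALSE)
  }
  env <- rbind(one(cx$alpha), one(cx$beta))
  env <- env[env$min_dist < radius, , drop = FALSE]
  env <- env[order(env$min_dist), , drop = FALSE]
  rownames(env) <- NULL
  env
}
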