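test_that("grid sizing follows (extent/spacing + 1)^3 with validation", {
  g <- fit_grid(c(0, 0, 0), spacing = 1, extent = 2)
  expect_equal(grid_point_count(g), 27)
  expect_equal(grid_points(g)[1, ], c(-1, -1, -1))
  expect_equal(grid_points(g)[27, ], c(1, 1, 1))
  expect_equal(grid_points(g, 2)[1, ], c(0, -1, -1))  # x varies fastest

  expect_error(fit_grid(c(0, 0, 0), spacing = 0, extent = 2), "positive")
  expect_error(fit_grid(c(0, 0, 0), spacing = 0.7, extent = 2),
               "does not divide")

  fine <- fit_grid(c(0, 0, 0), spacing = 0.1, extent = 32)
  expect_equal(fine$points_per_axis, 321L)
  expect_equal(grid_point_count(fine), 33076161)
})

test_that("grid points transform rigidly with a pose", {
  g <- fit_grid(c(1, 2, 3), spacing = 1, extent = 2)
  pts <- grid_points(g)
  expect_equal(transform_grid_points(pts, rigid_transform(diag(3))), pts)
  shifted <- transform_grid_points(pts,
                                   rigid_transform(diag(3), c(1, -2, 5)))
  expect_equal(shifted, sweep(pts, 2, c(1, -2, 5), "+"))
  # a rotation about a grid point fixes that point
  p <- pts[14, ]
  R <- rotation_from_euler_xyz(20, 30, 40)
  pose <- rigid_transform(R, p - drop(R %*% p))
  expect_equal(transform_grid_points(pts, pose)[14, ], p,
               tolerance = 1e-12)
})

test_that("the variance field matches the brute-force double-loop oracle", {
  set.seed(16)
  for (n in c(2, 3, 5)) {
    pts <- matrix(runif(24, -4, 4), ncol = 3)  # 8-point "grid"
    poses <- lapply(seq_len(n), function(i)
      rigid_transform(vdomgeom:::random_rotation(), rnorm(3, sd = 2)))
    positions <- lapply(poses, function(p) apply_transform(p, pts))
    f <- variance_field(positions)
    expect_equal(f$var, variance_field_oracle(positions),
                 tolerance = 1e-12)
  }
})

test_that("identical poses give a zero field and a degenerate CoR", {
  pts <- grid_points(fit_grid(c(0, 0, 0), 1, 2))
  poses <- rep(list(rigid_transform(diag(3), c(1, 1, 1))), 3)
  f <- variance_field(pts, poses = poses)
  expect_true(all(f$var == 0))
  expect_error(locate_cor(f, fit_grid(c(0, 0, 0), 1, 2)), "degenerate")
})

test_that("pure translations leave the field constant (no spurious CoR structure)", {
  set.seed(17)
  pts <- grid_points(fit_grid(c(0, 0, 0), 2, 8))
  poses <- lapply(1:4, function(i) rigid_transform(diag(3), rnorm(3, 5)))
  f <- variance_field(pts, poses = poses)
  expect_lt(max(f$var) - min(f$var), 1e-12)
})

test_that("a planted pivot is recovered within one grid spacing", {
  set.seed(18)
  pivot <- c(1.3, -0.7, 2.2)
  poses <- lapply(1:6, function(i) {
    R <- rotation_from_euler_xyz(runif(3, -15, 15))
    rigid_transform(R, pivot - drop(R %*% pivot))
  })
  grid <- fit_grid(c(1, -1, 2), spacing = 0.5, extent = 10)
  pts <- grid_points(grid)
  f <- variance_field(pts, poses = poses)
  res <- locate_cor(f, grid)
  # recovery error no worse than one grid spacing
  expect_lte(sqrt(sum((res$coordinate - pivot)^2)), 0.5)
  expect_equal(res$variance_at_min, min(f$var))
})

test_that("argmin ties break to the lowest index", {
  f <- structure(list(var = c(0.5, 0.2, 0.2, 0.9), n = 2,
                      exclude_self = FALSE), class = "variance_field")
  res <- locate_cor(f, matrix(1:12, ncol = 3, byrow = TRUE))
  expect_equal(res$i_min, 2L)
})

test_that("excluding self-pairs changes normalisation but not the argmin on planted data", {
  set.seed(19)
  pivot <- c(0.4, 0.1, -0.2)
  poses <- lapply(1:4, function(i) {
    R <- rotation_from_euler_xyz(runif(3, -20, 20))
    rigid_transform(R, pivot - drop(R %*% pivot))
  })
  grid <- fit_grid(c(0, 0, 0), 0.5, 4)
  pts <- grid_points(grid)
  f1 <- variance_field(pts, poses = poses)
  f2 <- variance_field(pts, poses = poses, exclude_self = TRUE)
  expect_false(isTRUE(all.equal(f1$var, f2$var)))
  expect_equal(which.min(f1$var), which.min(f2$var))
})

test_that("coarse-to-fine search agrees with exhaustive search", {
  ens <- planted_ensemble(synthetic_spec(n_structures = 6, n_clusters = 3,
                                         seed = 28))
  pipe <- pipeline_of(ens)
  center <- pipe$ref_cuboid$center
  ex <- cor_search(pipe$poses, center, spacing = 0.5, extent = 24,
                   strategy = "exhaustive", chunk_size = 50000L)
  cf <- cor_search(pipe$poses, center, spacing = 0.5, extent = 24,
                   strategy = "coarse2fine", coarse_spacing = 2,
                   refine_box = 4)
  expect_equal(cf$coordinate, ex$coordinate, tolerance = 1e-9)
})

test_that("the full pipeline recovers the planted pivot within grid spacing", {
  ens <- planted_ensemble(synthetic_spec(n_structures = 8, n_clusters = 3,
                                         seed = 29))
  pipe <- pipeline_of(ens)
  res <- run_cor(pipe, spacing = 0.1, extent = 32)
  expect_lt(sqrt(sum((res$cor$coordinate - ens$pivot)^2)), 0.1 * sqrt(3))
  expect_s3_class(res$environment, "data.frame")
  expect_gt(nrow(res$environment), 0)
})

test_that("the CoR residue environment is distance-sorted and radius-limited", {
  cx <- synth_complex(toy_domain(33, "alpha"), toy_domain(33, "beta"))
  ca1 <- cx$alpha$ca[5, ]
  env <- cor_environment(cx, ca1, radius = 1)
  expect_equal(nrow(env), 1)
  expect_equal(env$position, "5")
  expect_equal(env$chain_type, "alpha")
  expect_equal(nrow(cor_environment(cx, ca1, radius = 0)), 0)
  env8 <- cor_environment(cx, ca1, radius = 8)
  expect_false(is.unsorted(env8$min_dist))
})

test_that("interchain H-bond detection applies the heavy-atom cutoff in both directions", {
  mk_atoms <- function(name, resn, x, chain, element) {
    data.frame(atom_name = name, residue_name = resn, residue_number = 1,
               insert = "", chain_id = chain, element = element,
               x = x, y = 0, z = 0, altloc = "", occupancy = 1,
               stringsAsFactors = FALSE)
  }
  don <- mk_atoms("NE2", "GLN", 0, "A", "N")
  acc <- mk_atoms("OE1", "GLN", 3.4, "B", "O")
  hb <- detect_interchain_hbonds(don, acc)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$distance, 3.4)
  expect_equal(hb$donor_chain, "alpha")

  acc4 <- mk_atoms("OE1", "GLN", 4.0, "B", "O")
  expect_equal(nrow(detect_interchain_hbonds(don, acc4)), 0)
  expect_equal(nrow(detect_interchain_hbonds(don, acc4, cutoff = 4.5)), 1)

  # beta-side donor to alpha-side acceptor is also reported
  hb2 <- detect_interchain_hbonds(mk_atoms("OE1", "GLN", 0, "A", "O"),
                                  mk_atoms("NE2", "GLN", 3.0, "B", "N"))
  expect_equal(hb2$donor_chain, "beta")

  # glutamine with a missing side chain is flagged
  bare <- mk_atoms("CA", "GLN", 10, "A", "C")
  hb3 <- detect_interchain_hbonds(bare, acc)
  expect_equal(attr(hb3, "flagged")$alpha, "1")
})
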