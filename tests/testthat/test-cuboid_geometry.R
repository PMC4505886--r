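test_that("Euler decomposition handles canonical and composed rotations", {
  expect_equal(euler_xyz_from_rotation(diag(3)),
               c(phi = 0, psi = 0, theta = 0))
  expect_equal(euler_xyz_from_rotation(rotation_from_euler_xyz(90, 0, 0)),
               c(phi = 90, psi = 0, theta = 0), tolerance = 1e-12)
  # convention check: (0, 90, 0) carries e_z onto e_x
  expect_equal(drop(rotation_from_euler_xyz(0, 90, 0) %*% c(0, 0, 1)),
               c(1, 0, 0), tolerance = 1e-12)
  expect_error(euler_xyz_from_rotation(matrix(1, 3, 3)), "rotation")
})

test_that("compose-then-extract round-trips random triples to 1e-9 degrees", {
  set.seed(1)
  ang <- matrix(runif(600, -89.9, 89.9), ncol = 3)
  worst <- 0
  for (i in seq_len(nrow(ang))) {
    back <- euler_xyz_from_rotation(rotation_from_euler_xyz(ang[i, ]))
    worst <- max(worst, max(abs(back - ang[i, ])))
  }
  expect_lt(worst, 1e-9)
})

test_that("gimbal lock follows the phi := 0 convention and still reproduces the rotation", {
  for (psi in c(90, -90)) {
    R <- rotation_from_euler_xyz(35, psi, -70)
    e <- euler_xyz_from_rotation(R)
    expect_equal(unname(e[1]), 0)
    expect_equal(unname(e[2]), psi)
    expect_equal(rotation_from_euler_xyz(e), R, tolerance = 1e-9)
  }
})

test_that("the EAD is a metric on wrapped angle space", {
  expect_equal(euler_angle_distance(c(3, 4, 0), c(0, 0, 0)), 5)
  expect_equal(euler_angle_distance(c(12, -34, 56), c(12, -34, 56)), 0)
  # wrap: 179 vs -179 differ by 2 degrees, not 358
  expect_equal(euler_angle_distance(c(179, 0, 0), c(-179, 0, 0)), 2)

  set.seed(2)
  n <- 10000
  a <- random_euler_triples(n); b <- random_euler_triples(n)
  c3 <- random_euler_triples(n)
  dab <- dba <- dac <- dcb <- numeric(n)
  for (i in seq_len(n)) {
    dab[i] <- euler_angle_distance(a[i, ], b[i, ])
    dba[i] <- euler_angle_distance(b[i, ], a[i, ])
    dac[i] <- euler_angle_distance(a[i, ], c3[i, ])
    dcb[i] <- euler_angle_distance(c3[i, ], b[i, ])
  }
  expect_true(all(dab >= 0))
  expect_equal(dab, dba)
  expect_true(all(dab <= dac + dcb + 1e-9))   # triangle inequality
})

test_that("reference cuboid axes follow the anchor principal axes with a fixed sign convention", {
  # synthetic anchor cloud stretched x2 along y: first principal axis ~ e_y
  set.seed(3)
  cloud <- cbind(rnorm(60, sd = 2), rnorm(60, sd = 4), rnorm(60, sd = 1))
  atoms <- data.frame(atom_name = "CA", residue_name = "ALA",
                      residue_number = 1:60, insert = "", chain_id = "A",
                      element = "C", x = cloud[, 1], y = cloud[, 2],
                      z = cloud[, 3], altloc = "", occupancy = 1,
                      stringsAsFactors = FALSE)
  dom <- extract_variable_domain(atoms, NULL, "alpha")
  tmpl <- framework_template("alpha", rownames(dom$ca), dom$ca)
  cub <- build_reference_cuboid(dom, tmpl)
  ev <- eigen(stats::cov(cloud), symmetric = TRUE)$vectors[, 1]
  expect_gt(abs(sum(cub$axes[, 1] * ev)), 0.99)
  expect_equal(det(cub$axes), 1, tolerance = 1e-9)
  # extents cover every atom
  proj <- abs(sweep(cloud, 2, cub$center) %*% cub$axes)
  expect_true(all(proj <= rep(cub$half_extents + 1e-9,
                              each = nrow(proj))))

  # near-collinear anchors are degenerate
  lin <- data.frame(atom_name = "CA", residue_name = "ALA",
                    residue_number = 1:10, insert = "", chain_id = "A",
                    element = "C", x = 1:10, y = 0, z = 0, altloc = "",
                    occupancy = 1, stringsAsFactors = FALSE)
  ldom <- extract_variable_domain(lin, NULL, "alpha")
  ltmp <- list(anchor_coordinates = ldom$ca)
  class(ltmp) <- "framework_template"
  expect_error(build_reference_cuboid(ldom, ltmp), "degenerate")
})

test_that("beta cuboid placement reproduces the generating pose", {
  ens <- planted_ensemble(synthetic_spec(n_structures = 3, n_clusters = 1,
                                         seed = 8, intra_cluster_spread = 3))
  pipe <- pipeline_of(ens)
  ref_idx <- which(pipe$records$pdb_id == "REF0")
  # reference: placed cuboid identical to the reference cuboid
  cub_ref <- place_beta_cuboid(pipe$aligned[[ref_idx]], pipe$beta_template,
                               pipe$ref_cuboid)
  expect_equal(cub_ref$center, pipe$ref_cuboid$center, tolerance = 1e-9)
  expect_equal(cub_ref$axes, pipe$ref_cuboid$axes, tolerance = 1e-9)

  for (i in seq_along(ens$complexes)) {
    truth <- attr(ens$complexes[[i]], "truth")
    cub <- place_beta_cuboid(pipe$aligned[[i + 1]], pipe$beta_template,
                             pipe$ref_cuboid)
    pose <- attr(cub, "pose")
    expect_equal(pose$rotation, truth$pose$rotation, tolerance = 1e-6)
    expect_equal(pose$translation, truth$pose$translation,
                 tolerance = 1e-5)
    expect_equal(cub$center, apply_transform(truth$pose,
                                             pipe$ref_cuboid$center),
                 tolerance = 1e-6)
  }
})

test_that("a rotation through the cuboid center moves axes but not the center", {
  alpha <- toy_domain(41, "alpha"); beta <- toy_domain(41, "beta")
  base <- synth_complex(alpha, beta, c(0, 0, 0))
  mask <- remove_loops_and_turns(base$beta)
  pos <- names(mask)[mask]
  tmpl <- framework_template("beta", pos, base$beta$ca[pos, ])
  cub <- build_reference_cuboid(base$beta, tmpl)
  rotated <- synth_complex(alpha, toy_domain(41, "beta"), c(10, 0, 0),
                           pivot = cub$center)
  placed <- place_beta_cuboid(rotated, tmpl, cub)
  expect_equal(placed$center, cub$center, tolerance = 1e-6)
  expect_equal(placed$axes, rotation_from_euler_xyz(10, 0, 0) %*% cub$axes,
               tolerance = 1e-6)
})

test_that("pipeline-recovered Euler triples equal planted triples and are motion-invariant", {
  ens <- planted_ensemble(synthetic_spec(n_structures = 8, n_clusters = 2,
                                         seed = 10))
  pipe <- pipeline_of(ens)
  rec <- as.matrix(pipe$records[pipe$records$pdb_id != "REF0",
                                c("phi", "psi", "theta")])
  expect_lt(max(abs(rec - ens$angles)), 1e-6)

  # applying a fresh global motion to a raw input leaves the triple fixed
  set.seed(12)
  g <- rigid_transform(vdomgeom:::random_rotation(), runif(3, -50, 50))
  moved <- vdomgeom:::transform_complex(ens$complexes[[3]], g)
  e1 <- beta_euler(align_complex_on_alpha(ens$complexes[[3]],
                                          pipe$alpha_template)$complex,
                   pipe$beta_template)
  e2 <- beta_euler(align_complex_on_alpha(moved,
                                          pipe$alpha_template)$complex,
                   pipe$beta_template)
  expect_equal(e1, e2, tolerance = 1e-6)
})
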