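test_that("extended traces keep all positions; inserted coil is masked out", {
  dom <- straight_domain(30)
  mask <- remove_loops_and_turns(dom)
  expect_true(all(mask))

  # two extended strands bridged by a compact random-coil segment
  set.seed(42)
  coil <- matrix(runif(18, -1.2, 1.2), ncol = 3)
  coil[, 1] <- coil[, 1] + 13 * 3.8
  strand2 <- cbind(13 * 3.8 + 3.8 * (1:11), 0, 0)
  xyz <- rbind(cbind(3.8 * (1:13), 0, 0), coil, strand2)
  atoms <- data.frame(atom_name = "CA", residue_name = "ALA",
                      residue_number = seq_len(nrow(xyz)), insert = "",
                      chain_id = "A", element = "C", x = xyz[, 1],
                      y = xyz[, 2], z = xyz[, 3], altloc = "",
                      occupancy = 1, stringsAsFactors = FALSE)
  dom2 <- extract_variable_domain(atoms, NULL, "alpha")
  mask2 <- remove_loops_and_turns(dom2)
  expect_true(all(!mask2[15:18]))
  expect_true(all(mask2[c(1:11, 22:30)]))
})

test_that("short fragments cannot be masked", {
  expect_error(remove_loops_and_turns(straight_domain(5)),
               "at least 20")
})

test_that("the toy domain's strand cores are recovered by the mask", {
  dom <- toy_domain(seed = 1, chain_type = "alpha")
  truth <- attr(dom, "framework_mask")
  mask <- remove_loops_and_turns(dom)
  # interior strand residues must be kept, loop interiors dropped
  strand_runs <- rle(unname(truth))
  expect_gt(sum(mask & truth), 40)       # plenty of anchors survive
  expect_lt(sum(mask & !truth), 5)       # almost no loop residues kept
})

test_that("framework derivation converges immediately on exact copies", {
  dom <- toy_domain(seed = 2, chain_type = "alpha")
  tmpl <- derive_framework_subset(list(dom, dom, dom), "alpha")
  expect_s3_class(tmpl, "framework_template")
  expect_equal(attr(tmpl, "iterations"), 1L)
  expect_equal(attr(tmpl, "rmsd_variance"), 0)
  # idempotent: anchors equal the shared strand mask
  mask <- remove_loops_and_turns(dom)
  expect_setequal(tmpl$anchor_positions, names(mask)[mask])
})

test_that("perturbed regions are excluded from the converged subset", {
  dom <- toy_domain(seed = 2, chain_type = "beta")
  mask <- remove_loops_and_turns(dom)
  strand_pos <- names(mask)[mask]
  hit <- strand_pos[10:14]
  dom2 <- dom
  sel <- dom2$atoms$atom_name == "CA" &
    paste0(dom2$atoms$residue_number, dom2$atoms$insert) %in% hit
  dom2$atoms$z[sel] <- dom2$atoms$z[sel] + 5
  dom2$ca[hit, 3] <- dom2$ca[hit, 3] + 5
  tmpl <- derive_framework_subset(list(dom, dom2, dom), "beta")
  expect_false(any(hit %in% tmpl$anchor_positions))
  expect_gt(length(tmpl$anchor_positions), 20)
})

test_that("random clouds with no common core fail to converge", {
  set.seed(7)
  mk <- function() {
    atoms <- data.frame(atom_name = "CA", residue_name = "ALA",
                        residue_number = 1:40, insert = "", chain_id = "A",
                        element = "C",
                        x = cumsum(runif(40, 2.5, 3.8)),
                        y = cumsum(rnorm(40, 0, 2)),
                        z = cumsum(rnorm(40, 0, 2)),
                        altloc = "", occupancy = 1,
                        stringsAsFactors = FALSE)
    extract_variable_domain(atoms, NULL, "alpha")
  }
  err <- tryCatch(derive_framework_subset(list(mk(), mk()), "alpha",
                                          dev_cutoff = 0.3),
                  error = function(e) e)
  expect_s3_class(err, "vdg_convergence_error")
  expect_true(!is.null(err$anchors))   # diagnostics carry the last subset
})

test_that("superposition recovers identity, known transforms, and matches the closed-form oracle", {
  dom <- toy_domain(seed = 4, chain_type = "alpha")
  mask <- remove_loops_and_turns(dom)
  tmpl <- framework_template("alpha", names(mask)[mask],
                             dom$ca[names(mask)[mask], ])

  self <- superpose_on_template(dom, tmpl)
  expect_lt(self$rmsd, 1e-9)
  expect_equal(self$transform$rotation, diag(3), tolerance = 1e-9)

  R <- rotation_from_euler_xyz(25, -40, 65)
  tr <- rigid_transform(R, c(5, -3, 12))
  moved <- vdomgeom:::transform_domain(dom, tr)
  sup <- superpose_on_template(moved, tmpl)
  inv <- invert_transform(tr)
  expect_equal(sup$transform$rotation, inv$rotation, tolerance = 1e-6)
  expect_equal(sup$transform$translation, inv$translation,
               tolerance = 1e-6)

  # noisy case: rmsd must agree with an independent least-squares fit
  set.seed(9)
  noisy <- dom
  noisy$ca <- noisy$ca + matrix(rnorm(length(noisy$ca), sd = 0.1),
                                ncol = 3)
  sup_n <- superpose_on_template(noisy, tmpl)
  pos <- tmpl$anchor_positions
  fixed <- as.vector(t(tmpl$anchor_coordinates[pos, ]))
  mobile <- as.vector(t(noisy$ca[pos, ]))
  fitted <- bio3d::fit.xyz(fixed, mobile,
                           fixed.inds = seq_along(fixed),
                           mobile.inds = seq_along(mobile))
  oracle_rmsd <- sqrt(mean(rowSums(
    (matrix(fitted, ncol = 3, byrow = TRUE) -
       matrix(fixed, ncol = 3, byrow = TRUE))^2)))
  expect_equal(sup_n$rmsd, oracle_rmsd, tolerance = 1e-5)
  expect_lt(abs(sup_n$rmsd - 0.1 * sqrt(2 * (1 - 1 / length(pos)))), 0.05)
})

test_that("fewer than three matched anchors is underdetermined", {
  dom <- straight_domain(30)
  tmpl <- framework_template("alpha", c("1", "15", "30"),
                             dom$ca[c("1", "15", "30"), ])
  dom_short <- extract_variable_domain(
    dom$atoms[dom$atoms$residue_number <= 16, ], NULL, "alpha")
  expect_error(superpose_on_template(dom_short, tmpl), "underdetermined")
})

test_that("superposing A on B and B on A gives mutually inverse transforms", {
  a <- toy_domain(seed = 5, chain_type = "alpha")
  b <- vdomgeom:::transform_domain(
    a, rigid_transform(rotation_from_euler_xyz(15, 25, -35), c(4, 4, -2)))
  mask <- remove_loops_and_turns(a)
  pos <- names(mask)[mask]
  ta <- framework_template("alpha", pos, a$ca[pos, ])
  tb <- framework_template("alpha", pos, b$ca[pos, ])
  ab <- superpose_on_template(a, tb)$transform
  ba <- superpose_on_template(b, ta)$transform
  comp <- compose_transforms(ab, ba)
  expect_equal(comp$rotation, diag(3), tolerance = 1e-6)
  expect_equal(comp$translation, c(0, 0, 0), tolerance = 1e-6)
})

test_that("alpha alignment is exact and invariant to global rigid motion", {
  ens <- planted_ensemble(synthetic_spec(n_structures = 2, n_clusters = 1,
                                         seed = 6))
  pipe <- pipeline_of(ens)
  # reference complex is unchanged by its own alignment
  ri <- which(pipe$records$pdb_id == "REF0")
  expect_lt(pipe$records$rmsd_alpha[ri], 1e-9)
  expect_equal(pipe$aligned[[ri]]$alpha$ca, ens$reference$alpha$ca,
               tolerance = 1e-6, ignore_attr = TRUE)

  # translating an input complex leaves its aligned coordinates unchanged
  cx <- ens$complexes[[1]]
  shifted <- vdomgeom:::transform_complex(
    cx, rigid_transform(diag(3), c(10, 0, 0)))
  al1 <- align_complex_on_alpha(cx, pipe$alpha_template)$complex
  al2 <- align_complex_on_alpha(shifted, pipe$alpha_template)$complex
  expect_equal(al1$beta$ca, al2$beta$ca, tolerance = 1e-6,
               ignore_attr = TRUE)

  # ... and so does an arbitrary rigid motion
  set.seed(31)
  g <- rigid_transform(vdomgeom:::random_rotation(), runif(3, -30, 30))
  al3 <- align_complex_on_alpha(vdomgeom:::transform_complex(cx, g),
                                pipe$alpha_template)$complex
  expect_equal(al1$beta$ca, al3$beta$ca, tolerance = 1e-6,
               ignore_attr = TRUE)
})
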