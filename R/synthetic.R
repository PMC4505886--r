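## Synthetic two-domain complexes with known ground truth.
##
## The generator builds pseudo-immunoglobulin C-alpha point clouds (an
## extended-strand "framework" core plus compact decoy loops), pairs them
## into alpha/beta complexes, and plants the beta pose: a rotation by known
## xyz Euler angles about a known pivot. Ensembles add per-cluster angular
## offsets, Gaussian angular jitter, optional coordinate noise, and a random
## global rigid motion per structure. Every pipeline stage can therefore be
## checked against planted truth without structure downloads.

#' Synthetic ensemble specification
#'
#' Defaults describe the baseline study conditions used throughout the test
#' suite: a bound-ensemble-sized set of identical-clonotype groups whose
#' cluster centers sit at mutually equal Euler-angle distances, small
#' within-cluster angular jitter, a pivot in the interdomain interface, and
#' noise-free coordinates.
#'
#' @param n_structures Number of complexes.
#' @param n_clusters Number of planted geometry clusters.
#' @param cluster_center_angles n_clusters x 3 matrix of Euler triples
#'   (degrees); default: mutually equidistant centers 20 degrees apart.
#' @param intra_cluster_spread SD of the per-component Gaussian angular
#'   jitter (degrees).
#' @param pivot Common rotation pivot (reference frame, Angstrom).
#' @param coordinate_noise SD of isotropic coordinate noise (Angstrom).
#' @param seed Integer seed; the generator is a pure function of it.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_structures = 24, n_clusters = 3,
                           cluster_center_angles = NULL,
                           intra_cluster_spread = 0.5,
                           pivot = c(15, -2, 2.5),
                           coordinate_noise = 0, seed = 1) {
  if (is.null(cluster_center_angles))
    cluster_center_angles <- equidistant_centers(n_clusters, 20)
  cluster_center_angles <- matrix(as.numeric(cluster_center_angles),
                                  ncol = 3)
  stopifnot(nrow(cluster_center_angles) == n_clusters,
            intra_cluster_spread >= 0, coordinate_noise >= 0,
            length(pivot) == 3, n_structures >= 1)
  structure(list(n_structures = as.integer(n_structures),
                 n_clusters = as.integer(n_clusters),
                 cluster_center_angles = cluster_center_angles,
                 intra_cluster_spread = intra_cluster_spread,
                 pivot = as.numeric(pivot),
                 coordinate_noise = coordinate_noise,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

## Mutually equidistant Euler-triple centers: 1 cluster at the origin,
## 2 on an axis, 3 as an equilateral triangle, 4 as a regular tetrahedron;
## beyond that, points on a circle (equidistant only pairwise-adjacent).
equidistant_centers <- function(k, side = 20) {
  if (k == 1) return(matrix(0, 1, 3))
  if (k == 2) return(rbind(c(-side / 2, 0, 0), c(side / 2, 0, 0)))
  if (k == 3) {
    r <- side / sqrt(3)
    ang <- 2 * pi * (0:2) / 3
    return(cbind(r * cos(ang), r * sin(ang), 0))
  }
  if (k == 4) {
    v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
    return(v * side / (2 * sqrt(2)))
  }
  r <- side / (2 * sin(pi / k))
  ang <- 2 * pi * (seq_len(k) - 1) / k
  cbind(r * cos(ang), r * sin(ang), 0)
}

#' Generate a pseudo-immunoglobulin toy domain
#'
#' A ~100-residue C-alpha point cloud laid out as two stacked sheets of
#' extended strands (~3.4 A rise, the designated "framework") connected by
#' compact decoy loop segments, with small deterministic jitter. One
#' mid-domain framework residue is built as a glutamine with side-chain
#' NE2/OE1 atoms for hydrogen-bond tests.
#'
#' @param seed Integer seed (same seed, identical coordinates).
#' @param chain_type `"alpha"` or `"beta"`.
#' @param n_strands,strand_len,loop_len Layout parameters (residues).
#' @return A `variable_domain` with attribute `framework_mask` (logical per
#'   residue, `TRUE` on strand cores).
#' @export
toy_domain <- function(seed = 1, chain_type = c("alpha", "beta"),
                       n_strands = 8, strand_len = 10, loop_len = 5) {
  chain_type <- match.arg(chain_type)
  with_seed(seed + 1000L * (chain_type == "beta"), {
    coords <- NULL
    is_strand <- logical(0)
    for (s in seq_len(n_strands)) {
      sheet <- (s - 1) %/% (n_strands / 2)          # 0 or 1
      y <- ((s - 1) %% (n_strands / 2)) * 4.8 + sheet * 2.4
      z <- sheet * 5
      xs <- seq(0, by = 3.4, length.out = strand_len)
      if (s %% 2 == 0) xs <- rev(xs)
      strand <- cbind(xs, y, z) + matrix(stats::rnorm(3 * strand_len,
                                                      sd = 0.05),
                                         ncol = 3)
      if (!is.null(coords) && s >= 2) {
        # compact loop between previous strand end and this strand start
        a <- coords[nrow(coords), ]; b <- strand[1, ]
        tt <- seq_len(loop_len) / (loop_len + 1)
        loop <- outer(1 - tt, a) + outer(tt, b)
        bulge <- sin(pi * tt) * 2.5
        loop[, 3] <- loop[, 3] + bulge * (if (sheet == 0) -1 else 1)
        loop <- loop + matrix(stats::rnorm(3 * loop_len, sd = 0.2),
                              ncol = 3)
        coords <- rbind(coords, loop)
        is_strand <- c(is_strand, rep(FALSE, loop_len))
      }
      coords <- rbind(coords, strand)
      is_strand <- c(is_strand, rep(TRUE, strand_len))
    }
    n <- nrow(coords)
    resname <- ifelse(is_strand, "VAL", "GLY")
    qn_idx <- which(is_strand)[ceiling(sum(is_strand) / 2)]
    resname[qn_idx] <- "GLN"
    chain_id <- if (chain_type == "alpha") "A" else "B"
    atoms <- data.frame(atom_name = "CA", residue_name = resname,
                        residue_number = seq_len(n), insert = "",
                        chain_id = chain_id, element = "C",
                        x = coords[, 1], y = coords[, 2], z = coords[, 3],
                        altloc = "", occupancy = 1,
                        stringsAsFactors = FALSE)
    # glutamine side-chain donor/acceptor pair off the C-alpha
    qca <- coords[qn_idx, ]
    side <- rbind(
      data.frame(atom_name = "NE2", residue_name = "GLN",
                 residue_number = qn_idx, insert = "", chain_id = chain_id,
                 element = "N", x = qca[1] + 1.5, y = qca[2] - 2.5,
                 z = qca[3] + 0.5, altloc = "", occupancy = 1,
                 stringsAsFactors = FALSE),
      data.frame(atom_name = "OE1", residue_name = "GLN",
                 residue_number = qn_idx, insert = "", chain_id = chain_id,
                 element = "O", x = qca[1] - 0.5, y = qca[2] - 2.8,
                 z = qca[3] - 0.3, altloc = "", occupancy = 1,
                 stringsAsFactors = FALSE))
    atoms <- rbind(atoms, side)
    atoms <- atoms[order(atoms$residue_number), , drop = FALSE]
    dom <- extract_variable_domain(atoms, NULL, chain_type)
    attr(dom, "framework_mask") <- stats::setNames(is_strand,
                                                   as.character(seq_len(n)))
    dom
  })
}

#' Assemble a synthetic two-domain complex with a planted beta pose
#'
#' The beta domain is shifted into an interface-forming position opposite
#' the alpha domain, then rotated about `pivot` by the xyz-composed rotation
#' of `euler`. The planted pose (rotation and induced translation) is
#' stored as ground truth.
#'
#' @param alpha,beta `variable_domain` objects (e.g. from [toy_domain()]).
#' @param euler Planted Euler triple `c(phi, psi, theta)`, degrees.
#' @param pivot Rotation pivot, Angstrom.
#' @param pdb_id Identifier for the complex.
#' @param beta_offset Translation placing the unrotated beta domain
#'   relative to alpha.
#' @param bound_state,tcr_type Metadata passed to [tcr_complex()].
#' @return A `tcr_complex` with attribute `truth` (list: `euler`, `pivot`,
#'   `pose`).
#' @export
synth_complex <- function(alpha, beta, euler = c(0, 0, 0),
                          pivot = c(15, -2, 2.5), pdb_id = "SYN1",
                          beta_offset = c(0, -20, 0),
                          bound_state = "mhc1", tcr_type = "toy") {
  stopifnot(length(euler) == 3, length(pivot) == 3)
  beta <- transform_domain(beta, rigid_transform(diag(3), beta_offset))
  R <- rotation_from_euler_xyz(euler)
  pose <- rigid_transform(R, pivot - drop(R %*% pivot))
  beta <- transform_domain(beta, pose)
  cx <- tcr_complex(pdb_id, 1, alpha, beta, bound_state = bound_state,
                    species = "human", tcr_type = tcr_type)
  attr(cx, "truth") <- list(euler = as.numeric(euler),
                            pivot = as.numeric(pivot), pose = pose)
  cx
}

#' Generate a planted ensemble of synthetic complexes
#'
#' Structure `i` belongs to cluster `1 + (i - 1) %% n_clusters`; its planted
#' Euler triple is the cluster center plus independent per-component
#' Gaussian jitter. All structures share the alpha/beta toy domains (up to
#' optional coordinate noise) and the rotation pivot, and each receives a
#' random global rigid motion so that alignment is always exercised.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `complexes` (list of `tcr_complex`), `labels` (planted
#'   cluster ids), `angles` (planted Euler triples, n x 3), `pivot`, and
#'   `reference` (the unrotated reference complex, global motion identity).
#' @export
planted_ensemble <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  alpha0 <- toy_domain(spec$seed, "alpha")
  beta0 <- toy_domain(spec$seed, "beta")
  reference <- synth_complex(alpha0, beta0, c(0, 0, 0), spec$pivot,
                             pdb_id = "REF0")
  with_seed(spec$seed + 7L, {
    labels <- 1L + (seq_len(spec$n_structures) - 1L) %% spec$n_clusters
    angles <- spec$cluster_center_angles[labels, , drop = FALSE] +
      matrix(stats::rnorm(3 * spec$n_structures,
                          sd = spec$intra_cluster_spread), ncol = 3)
    complexes <- vector("list", spec$n_structures)
    for (i in seq_len(spec$n_structures)) {
      a <- alpha0; b <- beta0
      if (spec$coordinate_noise > 0) {
        a <- jitter_domain(a, spec$coordinate_noise)
        b <- jitter_domain(b, spec$coordinate_noise)
      }
      cx <- synth_complex(a, b, angles[i, ], spec$pivot,
                          pdb_id = sprintf("SYN%03d", i),
                          tcr_type = sprintf("type%02d", labels[i]))
      global <- rigid_transform(random_rotation(),
                                stats::runif(3, -20, 20))
      cx <- transform_complex(cx, global)
      attr(cx, "truth") <- c(attr(cx, "truth"),
                             list(cluster = labels[i], global = global))
      complexes[[i]] <- cx
    }
    list(complexes = complexes, labels = labels, angles = angles,
         pivot = spec$pivot, reference = reference, spec = spec)
  })
}

jitter_domain <- function(domain, sd) {
  xyz <- as.matrix(domain$atoms[, c("x", "y", "z")])
  xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = sd), ncol = 3)
  domain$atoms$x <- xyz[, 1]; domain$atoms$y <- xyz[, 2]
  domain$atoms$z <- xyz[, 3]
  domain$ca <- xyz[domain$atoms$atom_name == "CA", , drop = FALSE]
  rownames(domain$ca) <- domain$residues$position
  domain
}

#' Write an ensemble to PDB fixtures plus a truth table
#'
#' Each complex is written as a standard PDB file (`<pdb_id>.pdb`,
#' re-ingestible by [read_structure()]); planted poses, pivot, labels and
#' the seed go to `truth.json` when jsonlite is available, else
#' `truth.csv`.
#'
#' @param ensemble A [planted_ensemble()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_ensemble_fixtures <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cx in ensemble$complexes)
    write_domain_pdb(cx, file.path(dir, paste0(cx$pdb_id, ".pdb")))
  write_domain_pdb(ensemble$reference, file.path(dir, "REF0.pdb"))
  truth <- data.frame(pdb_id = vapply(ensemble$complexes, `[[`, "",
                                      "pdb_id"),
                      cluster = ensemble$labels,
                      phi = ensemble$angles[, 1],
                      psi = ensemble$angles[, 2],
                      theta = ensemble$angles[, 3])
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(list(seed = ensemble$spec$seed,
                              pivot = ensemble$pivot, truth = truth),
                         file.path(dir, "truth.json"), digits = NA)
  } else {
    utils::write.csv(truth, file.path(dir, "truth.csv"),
                     row.names = FALSE)
  }
  manifest <- data.frame(pdb_id = truth$pdb_id,
                         file = paste0(truth$pdb_id, ".pdb"),
                         bu_chains = "A:B", alpha_range = "", beta_range = "",
                         bound_state = "1", species = "h",
                         tcr_type = vapply(ensemble$complexes, `[[`, "",
                                           "tcr_type"))
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}
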