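## End-to-end orchestration.
##
## run_align / run_cluster / run_cor / run_conserve / run_simulate chain the
## modules into the standard workflow: derive framework templates, align
## every biological unit on its alpha domain, record beta-pose Euler
## triples, cluster the Euler-angle distances with bootstrap support, and
## search the grid for the common center of rotation. Each step works on
## in-memory objects and optionally writes machine-readable outputs.

#' Run the geometry pipeline on a set of complexes
#'
#' Derives alpha and beta framework templates (anchored on the reference
#' complex), aligns every complex on its alpha domain, and records each
#' beta-domain pose and Euler triple.
#'
#' @param complexes List of `tcr_complex` objects.
#' @param reference_id `pdb_id` of the reference structure (default: the
#'   first complex). The reference's own frame becomes the common reference
#'   frame; its beta Euler triple is (0, 0, 0) by construction.
#' @param dev_cutoff,max_iter Passed to [derive_framework_subset()].
#' @return List of class `geometry_pipeline`: `alpha_template`,
#'   `beta_template`, `ref_cuboid` (reference beta cuboid), `aligned`
#'   (aligned complexes), `poses` (beta [rigid_transform()]s), `records`
#'   (geometry table with superposition RMSDs), `reference_id`.
#' @export
tcr_geometry_pipeline <- function(complexes, reference_id = NULL,
                                  dev_cutoff = 1.0, max_iter = 20L) {
  stopifnot(length(complexes) >= 2)
  ids <- vapply(complexes, `[[`, "", "pdb_id")
  if (is.null(reference_id)) reference_id <- ids[1]
  ri <- which(ids == reference_id)[1]
  if (is.na(ri)) stop("reference '", reference_id, "' not in the set")

  alpha_tmpl <- derive_framework_subset(lapply(complexes, `[[`, "alpha"),
                                        "alpha", reference_index = ri,
                                        dev_cutoff = dev_cutoff,
                                        max_iter = max_iter)
  beta_tmpl <- derive_framework_subset(lapply(complexes, `[[`, "beta"),
                                       "beta", reference_index = ri,
                                       dev_cutoff = dev_cutoff,
                                       max_iter = max_iter)
  alpha_tmpl$reference_id <- reference_id
  beta_tmpl$reference_id <- reference_id
  ref_cuboid <- build_reference_cuboid(complexes[[ri]]$beta, beta_tmpl)

  aligned <- vector("list", length(complexes))
  poses <- vector("list", length(complexes))
  rows <- vector("list", length(complexes))
  for (i in seq_along(complexes)) {
    al <- align_complex_on_alpha(complexes[[i]], alpha_tmpl)
    pose <- beta_pose(al$complex, beta_tmpl)
    eul <- euler_xyz_from_rotation(pose$rotation)
    aligned[[i]] <- al$complex
    poses[[i]] <- pose
    rows[[i]] <- data.frame(
      pdb_id = complexes[[i]]$pdb_id,
      bu_index = as.character(complexes[[i]]$bu_index),
      phi = eul[1], psi = eul[2], theta = eul[3],
      bound_state = complexes[[i]]$bound_state,
      tcr_type = complexes[[i]]$tcr_type,
      rmsd_alpha = al$superposition$rmsd,
      rmsd_beta = attr(pose, "rmsd"),
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  structure(list(alpha_template = alpha_tmpl, beta_template = beta_tmpl,
                 ref_cuboid = ref_cuboid, aligned = aligned, poses = poses,
                 records = records, reference_id = reference_id),
            class = "geometry_pipeline")
}

#' @export
print.geometry_pipeline <- function(x, ...) {
  cat("Geometry pipeline: ", nrow(x$records), " biological units aligned ",
      "on reference ", x$reference_id, "\n", sep = "")
  cat("  alpha anchors: ", length(x$alpha_template$anchor_positions),
      ", beta anchors: ", length(x$beta_template$anchor_positions), "\n",
      sep = "")
  invisible(x)
}

#' Align a dataset and write the geometry table
#'
#' Loads every biological unit of a manifest (or takes a ready list of
#' complexes), runs [tcr_geometry_pipeline()], and writes the per-BU
#' geometry table plus a superposition log. Per-entry load failures are
#' logged and the run continues with the remaining entries.
#'
#' @param x Manifest path, `dataset_manifest`, or list of `tcr_complex`.
#' @param reference_id Reference structure id (default first).
#' @param out_dir Output directory for `geometry.csv` and `align_log.txt`;
#'   `NULL` writes nothing.
#' @param ... Passed to [tcr_geometry_pipeline()].
#' @return The `geometry_pipeline` (invisibly), with attribute `failures`
#'   (data.frame of entries that could not be loaded).
#' @export
run_align <- function(x, reference_id = NULL, out_dir = NULL, ...) {
  failures <- data.frame(pdb_id = character(0), error = character(0),
                         stringsAsFactors = FALSE)
  if (is.character(x)) x <- read_manifest(x)
  if (inherits(x, "dataset_manifest")) {
    manifest <- x
    dir <- attr(manifest, "manifest_dir")
    complexes <- list()
    for (i in seq_len(nrow(manifest))) {
      entry <- manifest[i, ]
      res <- tryCatch({
        f <- entry$file
        if (!grepl("^/", f)) f <- file.path(dir, f)
        enumerate_biological_units(read_structure(f), entry)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures <- rbind(failures,
                          data.frame(pdb_id = entry$pdb_id,
                                     error = conditionMessage(res),
                                     stringsAsFactors = FALSE))
      } else complexes <- c(complexes, res)
    }
  } else complexes <- x
  pipe <- tcr_geometry_pipeline(complexes, reference_id = reference_id,
                                ...)
  attr(pipe, "failures") <- failures
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(pipe$records, file.path(out_dir, "geometry.csv"),
                     row.names = FALSE)
    log <- c(sprintf("reference: %s", pipe$reference_id),
             sprintf("alpha anchors: %d",
                     length(pipe$alpha_template$anchor_positions)),
             sprintf("beta anchors: %d",
                     length(pipe$beta_template$anchor_positions)),
             sprintf("aligned: %d BU(s)", nrow(pipe$records)),
             sprintf("failed: %d entry/ies", nrow(failures)),
             if (nrow(failures))
               sprintf("  %s: %s", failures$pdb_id, failures$error))
    writeLines(log, file.path(out_dir, "align_log.txt"))
  }
  invisible(pipe)
}

#' Cluster a geometry table with bootstrap support
#'
#' Averages multi-BU structures into one unified geometry (default), builds
#' the pairwise EAD matrix, clusters it with Ward linkage, runs the
#' multiscale bootstrap, and extracts the significant clusters.
#'
#' @param records Geometry record table (or `geometry.csv` path, or a
#'   `geometry_pipeline`).
#' @param n_replicas,seed,resample Passed to [bootstrap_support()].
#' @param au_threshold Passed to [cut_significant_clusters()].
#' @param average Collapse BUs per structure first (default `TRUE`).
#' @param out_dir Optional output directory (`distance_matrix.csv`,
#'   `clusters.csv`, `dendrogram.nwk`).
#' @return List of class `cluster_run`: `records`, `distance`, `support`,
#'   `assignment`, `seed`, `n_replicas`.
#' @export
run_cluster <- function(records, n_replicas = 1000, seed = 1,
                        au_threshold = 0.95, average = TRUE,
                        resample = "structures", out_dir = NULL) {
  if (inherits(records, "geometry_pipeline")) records <- records$records
  if (is.character(records))
    records <- utils::read.csv(records, stringsAsFactors = FALSE,
                               colClasses = c(bu_index = "character"))
  if (nrow(records) < 2)
    stop("clustering needs at least 2 geometries; got ", nrow(records))
  if (average) records <- average_bu_all(records)
  D <- pairwise_ead_matrix(records)
  support <- bootstrap_support(records, n_replicas = n_replicas,
                               seed = seed, resample = resample)
  assignment <- cut_significant_clusters(support,
                                         au_threshold = au_threshold)
  out <- structure(list(records = records, distance = D,
                        support = support, assignment = assignment,
                        seed = seed, n_replicas = n_replicas),
                   class = "cluster_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(D, file.path(out_dir, "distance_matrix.csv"))
    utils::write.csv(
      data.frame(label = names(assignment$assignment),
                 cluster = assignment$assignment,
                 seed = seed, n_replicas = n_replicas,
                 au_threshold = assignment$au_threshold,
                 row.names = NULL),
      file.path(out_dir, "clusters.csv"), row.names = FALSE)
    write_support_newick(support, file.path(out_dir, "dendrogram.nwk"))
    ord <- support$hclust$order
    writeLines(as.character(ord), file.path(out_dir, "heatmap_order.txt"))
  }
  out
}

#' @export
print.cluster_run <- function(x, ...) {
  cat("Cluster run on ", nrow(x$records), " geometries (seed ", x$seed,
      ", ", x$n_replicas, " replicas/scale)\n", sep = "")
  print(x$assignment)
  invisible(x)
}

#' Locate the common center of rotation for an aligned set
#'
#' Runs the grid variance search over the beta poses of a pipeline result
#' (optionally restricted to bound or unbound structures) and reports the
#' CoR with its residue environment and the interchain hydrogen bonds of
#' the reference complex.
#'
#' @param pipe A `geometry_pipeline` from [run_align()].
#' @param subset `"all"`, `"bound"` or `"unbound"`.
#' @param spacing,extent,strategy,coarse_spacing,refine_box Passed to
#'   [cor_search()].
#' @param environment_radius Radius for [cor_environment()] (Angstrom).
#' @param hbond_cutoff Heavy-atom cutoff for
#'   [detect_interchain_hbonds()] (Angstrom).
#' @param out_dir Optional output directory (`cor_report.json` when
#'   jsonlite is available, plus `variance_field.csv`, `environment.csv`,
#'   `hbonds.csv`).
#' @return List of class `cor_run`: `cor` (the [locate_cor()] result),
#'   `environment`, `hbonds`, `subset`, `n`.
#' @export
run_cor <- function(pipe, subset = c("all", "bound", "unbound"),
                    spacing = 0.1, extent = 32,
                    strategy = "coarse2fine", coarse_spacing = 1.0,
                    refine_box = 3, environment_radius = 8,
                    hbond_cutoff = 3.5, out_dir = NULL) {
  subset <- match.arg(subset)
  stopifnot(inherits(pipe, "geometry_pipeline"))
  states <- pipe$records$bound_state
  keep <- switch(subset,
                 all = rep(TRUE, length(states)),
                 bound = states != "unbound",
                 unbound = states == "unbound")
  poses <- pipe$poses[keep]
  if (length(poses) < 2)
    stop("subset '", subset, "' holds ", length(poses),
         " structure(s); at least 2 required")
  cor <- cor_search(poses, pipe$ref_cuboid, spacing = spacing,
                    extent = extent, strategy = strategy,
                    coarse_spacing = coarse_spacing,
                    refine_box = refine_box, subset_used = subset)
  ri <- which(vapply(pipe$aligned, `[[`, "", "pdb_id") ==
                pipe$reference_id)[1]
  refcx <- pipe$aligned[[ri]]
  env <- cor_environment(refcx, cor$coordinate,
                         radius = environment_radius)
  hb <- detect_interchain_hbonds(refcx$alpha, refcx$beta,
                                 cutoff = hbond_cutoff)
  out <- structure(list(cor = cor, environment = env, hbonds = hb,
                        subset = subset, n = cor$n),
                   class = "cor_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    field <- attr(cor, "field"); gridpts <- attr(cor, "grid")
    if (!is.null(field))
      utils::write.csv(as.data.frame(field, gridpts),
                       file.path(out_dir, "variance_field.csv"),
                       row.names = FALSE)
    utils::write.csv(env, file.path(out_dir, "environment.csv"),
                     row.names = FALSE)
    utils::write.csv(hb, file.path(out_dir, "hbonds.csv"),
                     row.names = FALSE)
    if (requireNamespace("jsonlite", quietly = TRUE))
      jsonlite::write_json(
        list(subset = subset, n = cor$n, i_min = cor$i_min,
             coordinate = cor$coordinate,
             variance_at_min = cor$variance_at_min,
             spacing = spacing, extent = extent, strategy = strategy),
        file.path(out_dir, "cor_report.json"), auto_unbox = TRUE,
        digits = NA)
  }
  out
}

#' @export
print.cor_run <- function(x, ...) {
  print(x$cor)
  cat("  ", nrow(x$environment), " residue(s) in the CoR environment, ",
      nrow(x$hbonds), " interchain H-bond contact(s) in the reference\n",
      sep = "")
  invisible(x)
}

#' Tabulate conservation at an alignment position
#'
#' @param fasta Path to an aligned FASTA of V-segment sequences.
#' @param column Alignment column corresponding to the numbering position
#'   of interest (supply the column your alignment maps to IMGT position
#'   44).
#' @param position_label Reported label, e.g. `"IMGT 44"`.
#' @param out_csv Optional output CSV.
#' @return A [frequency_at_position()] table.
#' @export
run_conserve <- function(fasta, column, position_label = "IMGT 44",
                         out_csv = NULL) {
  ali <- read_aligned_fasta(fasta)
  tab <- frequency_at_position(ali, column, position_label)
  if (!is.null(out_csv)) {
    df <- as.data.frame(unclass(tab))
    df$position <- attr(tab, "position_label")
    df$n_sequences <- attr(tab, "n_sequences")
    df$n_gap <- attr(tab, "n_gap")
    utils::write.csv(df, out_csv, row.names = FALSE)
  }
  tab
}

#' Generate and write a synthetic fixture set
#'
#' @param out_dir Output directory.
#' @param ... Passed to [synthetic_spec()].
#' @return The [planted_ensemble()] result, invisibly.
#' @export
run_simulate <- function(out_dir, ...) {
  ens <- planted_ensemble(synthetic_spec(...))
  write_ensemble_fixtures(ens, out_dir)
  invisible(ens)
}
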