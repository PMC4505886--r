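## Conserved-framework superposition templates.
##
## The immunoglobulin-fold framework (the beta-sheet core of a V domain) is
## structurally conserved across receptors; its C-alpha positions serve as
## superposition anchors. Loops and turns (CDRs included) are removed first,
## then the anchor subset is refined iteratively until the set of positions
## used for superposition converges.

#' Mask loop and turn residues of a C-alpha trace
#'
#' Geometric extension detector: a residue is considered part of an extended
#' (strand-like) segment when the C-alpha span across a window of +/- 2
#' residues is at least `min_rise` Angstrom per backbone step. Extended
#' chain advances ~3.3 A per residue, helices ~1.5 A, turns less; the
#' default 2.75 A separates strand cores from loops and turns on C-alpha
#' traces. Terminal residues inherit the nearest interior assignment.
#'
#' @param domain A `variable_domain` with at least 20 residues.
#' @param min_rise Minimum span per backbone step (Angstrom).
#' @param window Half-width of the span window (residues).
#' @return Logical mask over the domain's residues (`TRUE` = kept strand
#'   core), named by position label.
#' @export
remove_loops_and_turns <- function(domain, min_rise = 2.75, window = 2L) {
  stopifnot(inherits(domain, "variable_domain"))
  ca <- domain$ca
  n <- nrow(ca)
  if (n < 20)
    stop("domain has ", n, " residues; at least 20 required for ",
         "secondary-structure masking")
  keep <- rep(NA, n)
  for (i in seq_len(n)) {
    w <- min(window, i - 1L, n - i)
    if (w == 0) next
    span <- sqrt(sum((ca[i + w, ] - ca[i - w, ])^2))
    keep[i] <- span >= min_rise * 2 * w
  }
  # terminal residues: copy nearest interior assignment
  if (is.na(keep[1])) keep[1] <- keep[2]
  if (is.na(keep[n])) keep[n] <- keep[n - 1]
  keep[is.na(keep)] <- FALSE
  if (!any(keep))
    stop("no extended secondary structure assignable in domain (empty mask)")
  names(keep) <- rownames(ca)
  keep
}

#' Framework superposition template
#'
#' @param chain_type `"alpha"` or `"beta"`.
#' @param anchor_positions Ordered residue position labels of the anchors.
#' @param anchor_coordinates n x 3 C-alpha coordinates of the anchors in the
#'   reference frame (Angstrom).
#' @param reference_id Identifier of the reference structure (default
#'   `"2bnu"`, the high-resolution reference used throughout).
#' @return An object of class `framework_template`.
#' @export
framework_template <- function(chain_type, anchor_positions,
                               anchor_coordinates, reference_id = "2bnu") {
  anchor_coordinates <- as.matrix(anchor_coordinates)
  stopifnot(chain_type %in% c("alpha", "beta"),
            length(anchor_positions) == nrow(anchor_coordinates),
            ncol(anchor_coordinates) == 3)
  if (length(anchor_positions) < 3)
    stop("a framework template needs at least 3 anchors")
  cc <- sweep(anchor_coordinates, 2, colMeans(anchor_coordinates))
  if (qr(cc)$rank < 2)
    stop("anchor coordinates are collinear; template is degenerate")
  rownames(anchor_coordinates) <- anchor_positions
  structure(list(chain_type = chain_type,
                 anchor_positions = as.character(anchor_positions),
                 anchor_coordinates = anchor_coordinates,
                 reference_id = reference_id),
            class = "framework_template")
}

#' @export
print.framework_template <- function(x, ...) {
  cat("Framework template (", x$chain_type, "): ",
      length(x$anchor_positions), " anchors on reference ",
      x$reference_id, "\n", sep = "")
  invisible(x)
}

#' Superpose a domain onto a framework template
#'
#' Residue correspondence is established by matching the domain's position
#' labels against the template's anchor positions; the matched C-alpha pairs
#' are then superposed by least squares (Kabsch). The returned transform
#' moves the domain into the template's (reference) frame.
#'
#' @param domain A `variable_domain`.
#' @param template A [framework_template()] of the same chain type.
#' @return A list of class `superposition_result`: `transform`
#'   ([rigid_transform()]), `rmsd` (Angstrom, residual over matched
#'   C-alphas), `matched` (data.frame of template/target positions).
#' @export
superpose_on_template <- function(domain, template) {
  stopifnot(inherits(domain, "variable_domain"),
            inherits(template, "framework_template"))
  if (domain$chain_type != template$chain_type)
    stop("chain type mismatch: domain is ", domain$chain_type,
         ", template is ", template$chain_type)
  pos <- intersect(template$anchor_positions, rownames(domain$ca))
  if (length(pos) < 3)
    stop("underdetermined superposition: only ", length(pos),
         " of ", length(template$anchor_positions), " anchors matched")
  fit <- kabsch(domain$ca[pos, , drop = FALSE],
                template$anchor_coordinates[pos, , drop = FALSE])
  structure(list(transform = fit$transform, rmsd = fit$rmsd,
                 matched = data.frame(template_position = pos,
                                      target_position = pos,
                                      stringsAsFactors = FALSE)),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat("Superposition: ", nrow(x$matched), " matched anchors, RMSD ",
      format(x$rmsd, digits = 4), " A\n", sep = "")
  invisible(x)
}

#' Derive the converged framework anchor subset
#'
#' Starting from the loop/turn-removed strand positions shared by every
#' domain, iterates superpose-all-on-reference / drop-deviating-anchors
#' until the anchor set no longer changes: at each iteration every domain is
#' superposed on the current subset, the per-position RMS fluctuation about
#' the ensemble mean is computed, and all anchors exceeding `dev_cutoff` are
#' dropped in one batch (largest deviation first). Convergence additionally
#' reports the variance of the per-domain superposition RMSDs.
#'
#' @param domains List of `variable_domain` objects of one chain type (the
#'   first, or the one matching `reference_index`, anchors the template).
#' @param chain_type `"alpha"` or `"beta"`.
#' @param reference_index Which domain provides the reference frame.
#' @param dev_cutoff Per-position RMS deviation cutoff (Angstrom) above
#'   which an anchor is dropped.
#' @param rmsd_var_tol Reported convergence diagnostic: variance of
#'   superposition RMSDs considered "low" (Angstrom^2).
#' @param max_iter Maximum refinement iterations.
#' @param mask_args Arguments passed on to [remove_loops_and_turns()].
#' @return A [framework_template()] with attributes `iterations`,
#'   `rmsd_variance` and `history` (anchor counts per iteration).
#' @export
derive_framework_subset <- function(domains, chain_type = NULL,
                                    reference_index = 1L,
                                    dev_cutoff = 1.0,
                                    rmsd_var_tol = 0.05,
                                    max_iter = 20L,
                                    mask_args = list()) {
  stopifnot(length(domains) >= 2)
  if (is.null(chain_type)) chain_type <- domains[[1]]$chain_type
  if (!all(vapply(domains, function(d) d$chain_type == chain_type, TRUE)))
    stop("all domains must be of chain type '", chain_type, "'")
  ref <- domains[[reference_index]]

  masks <- lapply(domains, function(d)
    do.call(remove_loops_and_turns, c(list(d), mask_args)))
  shared <- Reduce(intersect, lapply(domains, function(d) rownames(d$ca)))
  anchors <- rownames(ref$ca)[masks[[reference_index]]]
  anchors <- anchors[anchors %in% shared]
  for (i in seq_along(domains))
    anchors <- anchors[masks[[i]][anchors]]

  fail <- function(msg, anchors, iter) {
    cond <- structure(class = c("vdg_convergence_error", "error",
                                "condition"),
                      list(message = paste0(msg, " (iteration ", iter,
                                            ", ", length(anchors),
                                            " anchors left)"),
                           call = sys.call(-1), anchors = anchors,
                           iteration = iter))
    stop(cond)
  }

  history <- integer(0)
  rmsd_var <- NA_real_
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter)
      fail("framework subset did not converge within max_iter", anchors,
           iter - 1L)
    if (length(anchors) < 3)
      fail("no common structurally conserved core", anchors, iter)
    tmpl <- tryCatch(
      framework_template(chain_type, anchors,
                         ref$ca[anchors, , drop = FALSE],
                         reference_id = "local"),
      error = function(e) fail(conditionMessage(e), anchors, iter))
    fits <- lapply(domains, superpose_on_template, template = tmpl)
    coords <- lapply(seq_along(domains), function(i)
      apply_transform(fits[[i]]$transform,
                      domains[[i]]$ca[anchors, , drop = FALSE]))
    stack <- simplify2array(coords)            # n_anchor x 3 x n_domain
    mean_pos <- apply(stack, c(1, 2), mean)
    dev <- per_anchor_rms(stack, mean_pos)
    rmsds <- vapply(fits, `[[`, numeric(1), "rmsd")
    rmsd_var <- stats::var(rmsds)
    history <- c(history, length(anchors))
    drop_idx <- which(dev > dev_cutoff)
    if (length(drop_idx) == 0) break
    drop_idx <- drop_idx[order(-dev[drop_idx])]
    anchors <- anchors[-drop_idx]
  }

  out <- framework_template(chain_type, anchors,
                            ref$ca[anchors, , drop = FALSE],
                            reference_id = "ensemble-reference")
  attr(out, "iterations") <- iter
  attr(out, "rmsd_variance") <- rmsd_var
  attr(out, "rmsd_variance_tol") <- rmsd_var_tol
  attr(out, "rmsd_variance_low") <- is.finite(rmsd_var) &&
    rmsd_var <= rmsd_var_tol
  attr(out, "history") <- history
  out
}

## RMS fluctuation of each anchor about the ensemble-mean position.
per_anchor_rms <- function(stack, mean_pos) {
  n_anchor <- dim(stack)[1]; n_dom <- dim(stack)[3]
  out <- numeric(n_anchor)
  for (a in seq_len(n_anchor)) {
    d2 <- colSums((matrix(stack[a, , ], nrow = 3) - mean_pos[a, ])^2)
    out[a] <- sqrt(mean(d2))
  }
  out
}

#' Align a complex on its alpha domain
#'
#' Superposes the complex's alpha variable domain onto the alpha framework
#' template and applies the same rigid transform to every atom of the
#' complex (alpha, beta and context), producing a member of the
#' alpha-aligned set.
#'
#' @param cx A `tcr_complex`.
#' @param alpha_template Alpha-chain [framework_template()].
#' @return List with `complex` (the aligned copy) and `superposition` (the
#'   alpha [superpose_on_template()] result).
#' @export
align_complex_on_alpha <- function(cx, alpha_template) {
  stopifnot(inherits(cx, "tcr_complex"),
            alpha_template$chain_type == "alpha")
  sup <- superpose_on_template(cx$alpha, alpha_template)
  list(complex = transform_complex(cx, sup$transform), superposition = sup)
}
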