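## Euler-angle clustering.
##
## Geometry records (one Euler triple per biological unit, or per structure
## after BU averaging) are compared by the Euler-angle distance, clustered
## with Ward's minimum-variance method, and cluster significance is assessed
## with a multiscale bootstrap giving per-node approximately-unbiased (au)
## and bootstrap-probability (bp) support.

#' Build a geometry record table
#'
#' @param pdb_id,bu_index,euler,bound_state,tcr_type Per-record fields;
#'   `euler` is an n x 3 matrix (or length-3 vector) of degrees.
#' @return data.frame with columns `pdb_id`, `bu_index`, `phi`, `psi`,
#'   `theta`, `bound_state`, `tcr_type`.
#' @export
geometry_record <- function(pdb_id, bu_index, euler,
                            bound_state = NA_character_,
                            tcr_type = NA_character_) {
  if (is.null(dim(euler))) euler <- matrix(euler, ncol = 3, byrow = TRUE)
  data.frame(pdb_id = pdb_id, bu_index = as.character(bu_index),
             phi = euler[, 1], psi = euler[, 2], theta = euler[, 3],
             bound_state = bound_state, tcr_type = tcr_type,
             stringsAsFactors = FALSE)
}

record_angles <- function(records) {
  as.matrix(records[, c("phi", "psi", "theta")])
}

#' Average the biological units of one structure
#'
#' Collapses all BU records of a single structure into one artificial
#' unified geometry by componentwise averaging of the Euler angles. Angles
#' are averaged on the circle (componentwise differences to the first record
#' are wrapped before averaging), which coincides with the arithmetic mean
#' for the small angular spreads seen within one crystal.
#'
#' @param records Geometry records of a single `pdb_id`.
#' @return A one-row record with `bu_index = "averaged"`.
#' @export
average_bu <- function(records) {
  stopifnot(nrow(records) >= 1)
  if (length(unique(records$pdb_id)) != 1)
    stop("average_bu expects records of a single structure; got: ",
         paste(unique(records$pdb_id), collapse = ", "))
  ang <- record_angles(records)
  ref <- ang[1, ]
  mean_ang <- wrap_angle(ref + colMeans(wrap_angle(sweep(ang, 2, ref))))
  out <- records[1, , drop = FALSE]
  out$bu_index <- "averaged"
  out$phi <- mean_ang[1]; out$psi <- mean_ang[2]; out$theta <- mean_ang[3]
  rownames(out) <- NULL
  out
}

#' Average the biological units of every structure in a table
#'
#' @param records Geometry record table (any number of structures).
#' @return One averaged record per `pdb_id`, in first-appearance order.
#' @export
average_bu_all <- function(records) {
  ids <- unique(records$pdb_id)
  do.call(rbind, lapply(ids, function(id)
    average_bu(records[records$pdb_id == id, , drop = FALSE])))
}

record_labels <- function(records) {
  ids <- records$pdb_id
  if (anyDuplicated(ids))
    ids <- paste(ids, records$bu_index, sep = ".")
  ids
}

#' Pairwise Euler-angle distance matrix
#'
#' @param records Geometry record table (>= 2 rows). Row labels are
#'   `pdb_id`, suffixed with the BU index when a structure appears more than
#'   once.
#' @return Symmetric matrix of EADs in degrees with zero diagonal and
#'   dimnames set to the record labels.
#' @export
pairwise_ead_matrix <- function(records) {
  stopifnot(nrow(records) >= 2)
  labels <- record_labels(records)
  if (anyDuplicated(labels))
    stop("duplicate record labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  ang <- record_angles(records)
  n <- nrow(ang)
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    d <- sweep(ang[(i + 1):n, , drop = FALSE], 2, ang[i, ])
    D[i, (i + 1):n] <- sqrt(rowSums(wrap_angle(d)^2))
  }
  D + t(D)
}

#' Ward linkage of a distance matrix
#'
#' Agglomerative clustering with Ward's minimum-variance criterion via the
#' Lance-Williams update on squared dissimilarities (`stats::hclust`,
#' method `"ward.D2"`), the correct Ward formulation for a Euclidean metric
#' such as the EAD. Merges are deterministic (ties resolved to the
#' lowest-index pair by the agglomeration routine) and merge heights are
#' monotone non-decreasing.
#'
#' @param D Symmetric EAD matrix from [pairwise_ead_matrix()] (or a `dist`).
#' @return An `hclust` object.
#' @export
ward_linkage <- function(D) {
  if (!inherits(D, "dist")) {
    D <- as.matrix(D)
    stopifnot(nrow(D) == ncol(D), nrow(D) >= 2)
    if (any(!is.finite(D))) stop("distance matrix contains non-finite values")
    if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
    if (any(diag(D) != 0)) stop("distance matrix diagonal must be zero")
    D <- stats::as.dist(D)
  } else if (any(!is.finite(D))) {
    stop("distance matrix contains non-finite values")
  }
  stats::hclust(D, method = "ward.D2")
}

## Leaf label sets of every internal node of an hclust tree.
node_leaf_sets <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    m <- hc$merge[k, ]
    left <- if (m[1] < 0) hc$labels[-m[1]] else sets[[m[1]]]
    right <- if (m[2] < 0) hc$labels[-m[2]] else sets[[m[2]]]
    sets[[k]] <- sort(c(left, right))
  }
  sets
}

## EAD distance object for an angle matrix (rows = observations), optionally
## over a resampled set of angle components.
ead_dist <- function(ang, cols = 1:3) {
  n <- nrow(ang)
  D <- matrix(0, n, n)
  a <- ang[, cols, drop = FALSE]
  for (i in seq_len(n - 1)) {
    d <- sweep(a[(i + 1):n, , drop = FALSE], 2, a[i, ])
    D[i, (i + 1):n] <- sqrt(rowSums(wrap_angle(d)^2))
  }
  stats::as.dist(D + t(D))
}

#' Multiscale bootstrap support for Ward clusters
#'
#' Estimates per-node bootstrap probability (bp) and approximately-unbiased
#' (au) support for the Ward dendrogram of a geometry record table.
#' Resampling is repeated at several scales (resample sizes `round(r * n)`
#' for scale factors `r`); for each internal node of the original tree the
#' scale-wise clade frequencies are combined into an au value by weighted
#' least-squares fit of `qnorm(1 - bp)` against `v * sigma + c / sigma`
#' (`sigma = sqrt(n / n')`), giving `au = 1 - pnorm(v - c)`. The reported bp
#' is the clade frequency at the scale closest to 1.
#'
#' Two resampling units are available. `"structures"` (default) resamples
#' observations: a node counts as recovered in a replicate when the sampled
#' members of its clade form a clade in the replicate tree (only replicates
#' where the clade's sampled membership is a non-trivial proper subset are
#' informative). `"components"` resamples the three angle components, the
#' feature-dimension scheme of classical multiscale bootstrap; with only
#' three features it is statistically degenerate and is provided for
#' comparison only.
#'
#' @param records Geometry record table (>= 4 rows).
#' @param n_replicas Bootstrap replicates per scale (>= 100).
#' @param seed Integer seed; fixed seed gives identical support values.
#' @param scales Resample-size factors (default ten steps 0.5..1.4).
#' @param resample `"structures"` or `"components"`.
#' @return List of class `node_support`: `support` (data.frame `node`, `au`,
#'   `bp`, `n_informative`), `hclust` (the original tree), `leaf_sets`,
#'   `n_replicas`, `seed`, `resample`.
#' @export
bootstrap_support <- function(records, n_replicas = 1000, seed = 1,
                              scales = seq(0.5, 1.4, length.out = 10),
                              resample = c("structures", "components")) {
  resample <- match.arg(resample)
  if (n_replicas < 100)
    stop("n_replicas must be at least 100 for a usable support estimate")
  ang <- record_angles(records)
  labels <- record_labels(records)
  n <- nrow(ang)
  stopifnot(n >= 4)
  rownames(ang) <- labels
  D <- pairwise_ead_matrix(records)
  hc <- ward_linkage(D)
  sets <- node_leaf_sets(hc)
  n_nodes <- length(sets)

  n_feat <- if (resample == "structures") n else 3L
  sizes <- pmax(2L, as.integer(round(scales * n_feat)))
  hits <- matrix(0, n_nodes, length(sizes))
  trials <- matrix(0, n_nodes, length(sizes))

  with_seed(seed, {
    for (s in seq_along(sizes)) {
      m <- sizes[s]
      for (b in seq_len(n_replicas)) {
        if (resample == "structures") {
          idx <- sample.int(n, m, replace = TRUE)
          uniq <- sort(unique(idx))
          if (length(uniq) < 3) next
          sub <- ang[uniq, , drop = FALSE]
          # weight repeated draws so duplicated observations count
          w <- tabulate(match(idx, uniq), nbins = length(uniq))
          hc_b <- stats::hclust(ead_dist(sub), method = "ward.D2",
                                members = w)
          sets_b <- node_leaf_sets(
            structure(list(merge = hc_b$merge, labels = labels[uniq]),
                      class = "hclust"))
          keys_b <- vapply(sets_b, paste, "", collapse = "\r")
          sampled <- labels[uniq]
          for (k in seq_len(n_nodes)) {
            inter <- sort(intersect(sets[[k]], sampled))
            if (length(inter) < 2 || length(inter) >= length(sampled)) next
            trials[k, s] <- trials[k, s] + 1
            if (paste(inter, collapse = "\r") %in% keys_b)
              hits[k, s] <- hits[k, s] + 1
          }
        } else {
          cols <- sample.int(3L, m, replace = TRUE)
          hc_b <- stats::hclust(ead_dist(ang, cols), method = "ward.D2")
          sets_b <- node_leaf_sets(
            structure(list(merge = hc_b$merge, labels = labels),
                      class = "hclust"))
          keys_b <- vapply(sets_b, paste, "", collapse = "\r")
          for (k in seq_len(n_nodes)) {
            trials[k, s] <- trials[k, s] + 1
            if (paste(sets[[k]], collapse = "\r") %in% keys_b)
              hits[k, s] <- hits[k, s] + 1
          }
        }
      }
    }
  })

  sigma <- sqrt(n_feat / sizes)
  sup <- data.frame(node = seq_len(n_nodes), au = NA_real_, bp = NA_real_,
                    n_informative = rowSums(trials))
  near1 <- which.min(abs(sigma - 1))
  for (k in seq_len(n_nodes)) {
    bp_k <- ifelse(trials[k, ] > 0, hits[k, ] / trials[k, ], NA)
    sup$bp[k] <- if (trials[k, near1] > 0) bp_k[near1] else NA_real_
    sup$au[k] <- fit_au(bp_k, sigma, trials[k, ])
  }
  # the root clade (all leaves) is trivially supported
  sup$au[n_nodes] <- 1; sup$bp[n_nodes] <- 1
  structure(list(support = sup, hclust = hc, leaf_sets = sets,
                 n_replicas = n_replicas, seed = seed, resample = resample,
                 scales = scales),
            class = "node_support")
}

## Weighted least-squares au fit for one node (pvclust-style z-transform).
fit_au <- function(bp, sigma, trials) {
  ok <- !is.na(bp) & trials > 0
  if (!any(ok)) return(NA_real_)
  bp <- bp[ok]; sigma <- sigma[ok]; trials <- trials[ok]
  eps <- 1 / (max(trials) + 1)
  if (all(bp >= 1 - 1e-12)) return(1)
  if (all(bp <= 1e-12)) return(0)
  bpc <- pmin(pmax(bp, eps), 1 - eps)
  z <- stats::qnorm(1 - bpc)
  X <- cbind(sigma, 1 / sigma)
  w <- trials * stats::dnorm(z)^2 / (bpc * (1 - bpc))
  fit <- tryCatch(stats::lm.wfit(X, z, w), error = function(e) NULL)
  if (is.null(fit) || anyNA(fit$coefficients)) {
    # degenerate design (single usable scale): fall back to bp nearest 1
    return(1 - bpc[which.min(abs(sigma - 1))])
  }
  v <- fit$coefficients[1]; cc <- fit$coefficients[2]
  unname(1 - stats::pnorm(v - cc))
}

#' @export
print.node_support <- function(x, ...) {
  cat("Multiscale bootstrap support (", x$resample, " resampling, ",
      x$n_replicas, " replicates/scale, seed ", x$seed, ")\n", sep = "")
  print(round(x$support[, c("node", "au", "bp")], 3))
  invisible(x)
}

#' Extract significant clusters from a supported dendrogram
#'
#' Maximal internal nodes (excluding the root, whose clade is the full set)
#' with `au >= au_threshold` become clusters; every leaf not covered by a
#' significant node is assigned to its own singleton cluster.
#'
#' @param support A [bootstrap_support()] result (carries the dendrogram).
#' @param au_threshold Significance threshold in (0, 1), default 0.95.
#' @return List of class `cluster_assignment`: `assignment` (named integer
#'   vector label -> cluster id), `n_clusters`, `significant_nodes`,
#'   `au_threshold`.
#' @export
cut_significant_clusters <- function(support, au_threshold = 0.95) {
  stopifnot(inherits(support, "node_support"))
  if (!is.numeric(au_threshold) || au_threshold <= 0 || au_threshold >= 1)
    stop("au_threshold must lie strictly between 0 and 1")
  hc <- support$hclust
  sets <- support$leaf_sets
  au <- support$support$au
  n_nodes <- length(sets)
  root <- n_nodes
  sig <- which(!is.na(au) & au >= au_threshold)
  sig <- setdiff(sig, root)
  # maximal: no significant strict ancestor
  is_ancestor <- function(a, b) all(sets[[b]] %in% sets[[a]]) &&
    length(sets[[a]]) > length(sets[[b]])
  maximal <- sig[vapply(sig, function(k)
    !any(vapply(sig, is_ancestor, TRUE, b = k)), TRUE)]
  maximal <- sort(maximal)
  labels <- hc$labels
  assignment <- stats::setNames(rep(NA_integer_, length(labels)), labels)
  cid <- 0L
  for (k in maximal) {
    cid <- cid + 1L
    assignment[sets[[k]]] <- cid
  }
  for (l in labels[is.na(assignment)]) {
    cid <- cid + 1L
    assignment[l] <- cid
  }
  structure(list(assignment = assignment,
                 n_clusters = cid,
                 n_significant = length(maximal),
                 significant_nodes = maximal,
                 au_threshold = au_threshold),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("Cluster assignment: ", x$n_significant, " significant cluster(s) at ",
      "au >= ", x$au_threshold, ", ", x$n_clusters,
      " cluster(s) total incl. singletons\n", sep = "")
  invisible(x)
}

#' Export a supported dendrogram as Newick
#'
#' Internal nodes are annotated with their au/bp support (percent,
#' `au|bp`); branch lengths are the Ward merge-height differences.
#'
#' @param support A [bootstrap_support()] result.
#' @param path Output file; if `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to `path`.
#' @export
write_support_newick <- function(support, path = NULL) {
  hc <- support$hclust
  au <- support$support$au
  bp <- support$support$bp
  phy <- ape::as.phylo(hc)
  # ape orders internal nodes root-first; map hclust merge rows to phylo
  # internal nodes via their leaf sets
  sets <- support$leaf_sets
  tip_sets <- lapply(seq_len(phy$Nnode), function(j) {
    node <- length(phy$tip.label) + j
    sort(phy$tip.label[tips_under(phy, node)])
  })
  keys_h <- vapply(sets, paste, "", collapse = "\r")
  keys_p <- vapply(tip_sets, paste, "", collapse = "\r")
  idx <- match(keys_p, keys_h)
  lab <- ifelse(is.na(idx), "",
                sprintf("%.0f|%.0f", 100 * au[idx], 100 * bp[idx]))
  phy$node.label <- lab
  nwk <- ape::write.tree(phy)
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}

tips_under <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(node)
  kids <- phy$edge[phy$edge[, 1] == node, 2]
  unlist(lapply(kids, tips_under, phy = phy))
}
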