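## Structure input/output.
##
## Parsing of PDB and mmCIF files is delegated to bio3d; this module layers
## the dataset-manifest logic on top: altloc resolution, per-biological-unit
## enumeration of alpha/beta variable-domain pairs, and domain extraction.
## All internal residue indexing is 0-based ordinal position within the
## extracted domain; author numbering (with insertion codes) is preserved as
## the position label used for cross-structure correspondence.

#' Read a structure file into per-chain atom models
#'
#' Reads a PDB or mmCIF file (dispatch on extension, `.cif`/`.mmcif` vs
#' anything else) and returns one atom table per chain. Alternate locations
#' are resolved to a single conformer per residue: the altloc whose atoms
#' carry the highest summed occupancy is kept; ties are broken by the
#' alphabetically first altloc identifier.
#'
#' @param path Path to a PDB or mmCIF file.
#' @return A named list of data.frames (one per chain, named by chain ID)
#'   with columns `atom_name`, `residue_name`, `residue_number`, `insert`,
#'   `chain_id`, `element`, `x`, `y`, `z`, `altloc`, `occupancy`. The file
#'   path is attached as attribute `"path"`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0)
    stop("parse error in '", path, "': file is empty (no ATOM records)")
  is_cif <- grepl("\\.(cif|mmcif)(\\.gz)?$", path, ignore.case = TRUE)
  pdb <- tryCatch(
    if (is_cif) bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE)
    else bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  atoms <- pdb$atom
  if (is.null(atoms) || nrow(atoms) == 0)
    stop("parse error in '", path, "': no ATOM records parsed")
  atoms <- data.frame(
    atom_name = atoms$elety,
    residue_name = atoms$resid,
    residue_number = atoms$resno,
    insert = ifelse(is.na(atoms$insert), "", atoms$insert),
    chain_id = ifelse(is.na(atoms$chain), "", atoms$chain),
    element = if (!is.null(atoms$elesy)) ifelse(is.na(atoms$elesy), "", atoms$elesy) else "",
    x = atoms$x, y = atoms$y, z = atoms$z,
    altloc = ifelse(is.na(atoms$alt), "", atoms$alt),
    occupancy = ifelse(is.na(atoms$o), 1, atoms$o),
    stringsAsFactors = FALSE)
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("parse error in '", path, "': non-finite coordinates")
  atoms <- resolve_altlocs(atoms)
  chains <- split(atoms, atoms$chain_id)
  chains <- lapply(chains, function(d) { rownames(d) <- NULL; d })
  attr(chains, "path") <- path
  chains
}

## Keep one conformer per residue: the altloc with the highest summed
## occupancy; ties go to the alphabetically first identifier. Blank-altloc
## atoms are always kept.
resolve_altlocs <- function(atoms) {
  has_alt <- atoms$altloc != ""
  if (!any(has_alt)) return(atoms)
  key <- paste(atoms$chain_id, atoms$residue_number, atoms$insert, sep = "|")
  keep <- rep(TRUE, nrow(atoms))
  for (k in unique(key[has_alt])) {
    sel <- key == k & has_alt
    occ <- tapply(atoms$occupancy[sel], atoms$altloc[sel], sum)
    occ <- occ[order(-occ, names(occ))]
    keep[sel] <- atoms$altloc[sel] == names(occ)[1]
  }
  out <- atoms[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract a variable domain from a chain model
#'
#' Restricts a chain atom table to the author-numbered residue range of the
#' variable domain (the constant domain is truncated) and wraps it as a
#' `variable_domain` object. Residues inside the range with no resolvable
#' C-alpha atom are counted as missing and flagged.
#'
#' @param chain A per-chain atom data.frame from [read_structure()].
#' @param range Length-2 integer vector `c(first, last)` in author numbering,
#'   or `NULL` to keep the whole chain.
#' @param chain_type `"alpha"` or `"beta"`.
#' @return A `variable_domain`: list with `chain_type`, `atoms` (atom table),
#'   `residues` (per-residue table with `position` labels), `ca` (n x 3
#'   C-alpha matrix, rownames = position labels), `source_chain_id`, and
#'   `n_missing` (residue numbers in range without a C-alpha).
#' @export
extract_variable_domain <- function(chain, range = NULL,
                                    chain_type = c("alpha", "beta")) {
  chain_type <- match.arg(chain_type)
  stopifnot(is.data.frame(chain), nrow(chain) > 0)
  atoms <- chain
  if (!is.null(range)) {
    stopifnot(length(range) == 2, range[1] <= range[2])
    atoms <- atoms[atoms$residue_number >= range[1] &
                   atoms$residue_number <= range[2], , drop = FALSE]
  }
  ca <- atoms[atoms$atom_name == "CA", , drop = FALSE]
  if (nrow(ca) == 0)
    stop("domain extraction failed: no C-alpha atoms in range [",
         paste(range, collapse = ", "), "] of chain '", chain$chain_id[1], "'")
  ord <- order(ca$residue_number, ca$insert)
  ca <- ca[ord, , drop = FALSE]
  position <- paste0(ca$residue_number, ca$insert)
  if (anyDuplicated(position))
    stop("duplicate residue positions after altloc resolution in chain '",
         chain$chain_id[1], "'")
  residues <- data.frame(position = position,
                         residue_number = ca$residue_number,
                         insert = ca$insert,
                         residue_name = ca$residue_name,
                         stringsAsFactors = FALSE)
  cam <- as.matrix(ca[, c("x", "y", "z")])
  rownames(cam) <- position
  n_missing <- if (is.null(range)) 0L else
    as.integer(range[2] - range[1] + 1 - length(unique(ca$residue_number)))
  structure(list(chain_type = chain_type,
                 atoms = atoms,
                 residues = residues,
                 ca = cam,
                 source_chain_id = chain$chain_id[1],
                 n_missing = n_missing),
            class = "variable_domain")
}

#' @export
print.variable_domain <- function(x, ...) {
  cat("Variable domain (", x$chain_type, "), chain ", x$source_chain_id,
      ": ", nrow(x$residues), " residues, ", nrow(x$atoms), " atoms",
      if (x$n_missing > 0) paste0(" (", x$n_missing, " missing in range)"),
      "\n", sep = "")
  invisible(x)
}

#' Construct a TCR complex (one biological unit)
#'
#' @param pdb_id 4-character structure identifier.
#' @param bu_index Biological-unit index (integer >= 1).
#' @param alpha,beta `variable_domain` objects of the respective chain type.
#' @param bound_state One of `"unbound"`, `"mhc1"`, `"mhc2"`,
#'   `"superantigen"`.
#' @param species `"human"` or `"mouse"`.
#' @param tcr_type Receptor clonotype label (free text).
#' @param context Optional atom data.frame of non-TCR chains (MHC, peptide)
#'   kept for environment analyses but excluded from all superpositions.
#' @return An object of class `tcr_complex`.
#' @export
tcr_complex <- function(pdb_id, bu_index, alpha, beta,
                        bound_state = c("unbound", "mhc1", "mhc2",
                                        "superantigen"),
                        species = c("human", "mouse"),
                        tcr_type = NA_character_, context = NULL) {
  bound_state <- match.arg(bound_state)
  species <- match.arg(species)
  stopifnot(inherits(alpha, "variable_domain"),
            inherits(beta, "variable_domain"),
            alpha$chain_type == "alpha", beta$chain_type == "beta",
            bu_index >= 1)
  structure(list(pdb_id = pdb_id, bu_index = as.integer(bu_index),
                 alpha = alpha, beta = beta, bound_state = bound_state,
                 species = species, tcr_type = tcr_type, context = context),
            class = "tcr_complex")
}

#' @export
print.tcr_complex <- function(x, ...) {
  cat("TCR complex ", x$pdb_id, " BU ", x$bu_index, " (", x$bound_state,
      ", ", x$species, if (!is.na(x$tcr_type)) paste0(", ", x$tcr_type),
      ")\n", sep = "")
  invisible(x)
}

#' Read a dataset manifest
#'
#' The manifest is a tab-separated table with one row per structure entry:
#' columns `pdb_id`, `file` (structure file, relative to the manifest unless
#' absolute), `bu_chains` (per-BU alpha:beta chain pairs, e.g. `"A:B;C:D"`),
#' `alpha_range` / `beta_range` (author-numbered `first-last`, empty = whole
#' chain), `bound_state` (`u`, `1`, `2`, `s` or the long names), `species`
#' (`h`/`m`), `tcr_type`, and optional `subtype`.
#'
#' @param path Path to the manifest TSV.
#' @return A data.frame of class `dataset_manifest` with attribute
#'   `"manifest_dir"`.
#' @export
read_manifest <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character", comment.char = "#")
  required <- c("pdb_id", "bu_chains", "bound_state", "species", "tcr_type")
  missing <- setdiff(required, names(m))
  if (length(missing))
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(m$pdb_id))
    stop("manifest has duplicate pdb_id entries")
  m$bound_state <- decode_bound_state(m$bound_state)
  m$species <- c(h = "human", m = "mouse",
                 human = "human", mouse = "mouse")[tolower(m$species)]
  if (anyNA(m$species)) stop("manifest has unrecognised species codes")
  attr(m, "manifest_dir") <- dirname(normalizePath(path))
  class(m) <- c("dataset_manifest", class(m))
  m
}

decode_bound_state <- function(x) {
  map <- c(u = "unbound", "1" = "mhc1", "2" = "mhc2", s = "superantigen",
           unbound = "unbound", mhc1 = "mhc1", mhc2 = "mhc2",
           superantigen = "superantigen")
  out <- map[tolower(x)]
  if (anyNA(out))
    stop("unrecognised bound_state code(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  unname(out)
}

parse_range <- function(x) {
  if (is.null(x) || is.na(x) || x == "") return(NULL)
  parts <- as.integer(strsplit(x, "-", fixed = TRUE)[[1]])
  if (length(parts) != 2 || anyNA(parts)) stop("bad range spec: ", x)
  parts
}

#' Enumerate the biological units of a manifest entry
#'
#' Builds one [tcr_complex()] per alpha:beta chain pair listed in the entry's
#' `bu_chains` field. Non-TCR chains are retained as context atoms but never
#' enter superpositions. Each biological unit is treated as an independent
#' structure downstream.
#'
#' @param chains Per-chain models from [read_structure()].
#' @param entry One manifest row (data.frame or list) with fields as in
#'   [read_manifest()].
#' @return List of `tcr_complex` objects, one per biological unit.
#' @export
enumerate_biological_units <- function(chains, entry) {
  entry <- as.list(entry)
  if (is.null(entry$bu_chains) || is.na(entry$bu_chains) ||
      entry$bu_chains == "")
    stop("manifest entry '", entry$pdb_id,
         "' does not name its biological-unit chains")
  pairs <- strsplit(strsplit(entry$bu_chains, ";", fixed = TRUE)[[1]],
                    ":", fixed = TRUE)
  arange <- parse_range(entry$alpha_range)
  brange <- parse_range(entry$beta_range)
  lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    if (length(p) != 2)
      stop("bad bu_chains spec in entry '", entry$pdb_id, "'")
    for (cid in p)
      if (!cid %in% names(chains))
        stop("manifest mismatch: chain '", cid, "' of entry '",
             entry$pdb_id, "' absent from structure file")
    alpha <- extract_variable_domain(chains[[p[1]]], arange, "alpha")
    beta <- extract_variable_domain(chains[[p[2]]], brange, "beta")
    ctx_ids <- setdiff(names(chains), p)
    context <- if (length(ctx_ids))
      do.call(rbind, chains[ctx_ids]) else NULL
    tcr_complex(entry$pdb_id, i, alpha, beta,
                bound_state = entry$bound_state,
                species = entry$species,
                tcr_type = if (is.null(entry$tcr_type)) NA_character_
                           else entry$tcr_type,
                context = context)
  })
}

#' Load every biological unit of a manifest
#'
#' @param manifest A [read_manifest()] table.
#' @param dir Directory holding the structure files; defaults to the
#'   manifest's own directory.
#' @return List of `tcr_complex` objects across all entries.
#' @export
load_manifest_complexes <- function(manifest, dir = NULL) {
  if (is.null(dir)) dir <- attr(manifest, "manifest_dir")
  out <- list()
  for (i in seq_len(nrow(manifest))) {
    entry <- manifest[i, ]
    f <- entry$file
    if (!grepl("^/", f)) f <- file.path(dir, f)
    chains <- read_structure(f)
    out <- c(out, enumerate_biological_units(chains, entry))
  }
  out
}

#' Write a variable domain (or complex) to a PDB file
#'
#' Writes the domain's atom records in standard PDB format for inspection or
#' re-ingestion; coordinates round-trip at PDB precision (3 decimals).
#'
#' @param x A `variable_domain` or `tcr_complex`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_domain_pdb <- function(x, path) {
  atoms <- if (inherits(x, "tcr_complex"))
    rbind(x$alpha$atoms, x$beta$atoms) else x$atoms
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
                   resno = atoms$residue_number,
                   resid = atoms$residue_name,
                   eleno = seq_len(nrow(atoms)),
                   elety = atoms$atom_name,
                   chain = atoms$chain_id,
                   insert = ifelse(atoms$insert == "", NA, atoms$insert),
                   o = atoms$occupancy,
                   elesy = atoms$element)
  invisible(path)
}

## Replace a domain's coordinates (atoms, ca) with transformed ones.
transform_domain <- function(domain, transform) {
  xyz <- as.matrix(domain$atoms[, c("x", "y", "z")])
  xyz <- apply_transform(transform, xyz)
  domain$atoms$x <- xyz[, 1]; domain$atoms$y <- xyz[, 2]
  domain$atoms$z <- xyz[, 3]
  domain$ca <- apply_transform(transform, domain$ca)
  domain
}

## Apply one rigid transform to every atom of a complex (both domains and
## any context chains).
transform_complex <- function(cx, transform) {
  cx$alpha <- transform_domain(cx$alpha, transform)
  cx$beta <- transform_domain(cx$beta, transform)
  if (!is.null(cx$context)) {
    xyz <- apply_transform(transform,
                           as.matrix(cx$context[, c("x", "y", "z")]))
    cx$context$x <- xyz[, 1]; cx$context$y <- xyz[, 2]
    cx$context$z <- xyz[, 3]
  }
  cx
}
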