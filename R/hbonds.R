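## Interchain hydrogen-bond detection.
##
## Crystal structures rarely carry hydrogens, so the criterion is a pure
## heavy-atom donor-acceptor distance cutoff (default 3.5 A) with no angle
## term. Donor/acceptor roles follow standard side-chain chemistry plus the
## backbone amide N (donor) and carbonyl O (acceptor).

DONOR_ATOMS <- list(
  ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), LYS = "NZ", SER = "OG", THR = "OG1",
  TRP = "NE1", TYR = "OH", CYS = "SG")

ACCEPTOR_ATOMS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH", MET = "SD")

polar_atoms <- function(atoms, role = c("donor", "acceptor"),
                        include_backbone = TRUE) {
  role <- match.arg(role)
  tab <- if (role == "donor") DONOR_ATOMS else ACCEPTOR_ATOMS
  bb <- if (role == "donor") "N" else c("O", "OXT")
  sel <- logical(nrow(atoms))
  for (res in names(tab))
    sel <- sel | (atoms$residue_name == res & atoms$atom_name %in% tab[[res]])
  if (include_backbone) sel <- sel | atoms$atom_name %in% bb
  atoms[sel, , drop = FALSE]
}

## Residues whose side chain should provide donors/acceptors but lacks the
## expected atoms (unresolved side chains) -- flagged, not silently dropped.
flag_incomplete_sidechains <- function(atoms) {
  expected <- unique(c(names(DONOR_ATOMS), names(ACCEPTOR_ATOMS)))
  flags <- character(0)
  key <- paste0(atoms$residue_number, atoms$insert)
  for (k in unique(key)) {
    res <- atoms[key == k, , drop = FALSE]
    rn <- res$residue_name[1]
    if (!rn %in% expected) next
    want <- unique(c(DONOR_ATOMS[[rn]], ACCEPTOR_ATOMS[[rn]]))
    if (!all(want %in% res$atom_name)) flags <- c(flags, k)
  }
  flags
}

#' Detect interchain hydrogen bonds
#'
#' All donor-acceptor heavy-atom pairs across the two chains whose distance
#' does not exceed `cutoff`, in both directions (alpha donor / beta acceptor
#' and vice versa). Residues with missing polar side-chain atoms are
#' reported in the `flagged` attribute.
#'
#' @param alpha,beta `variable_domain` objects (or plain atom data.frames)
#'   of the two chains.
#' @param cutoff Heavy-atom distance cutoff in Angstrom (default 3.5).
#' @param include_backbone Include backbone N/O as donors/acceptors.
#' @return data.frame with one row per contact: `donor_chain`,
#'   `donor_position`, `donor_residue`, `donor_atom`, `acceptor_chain`,
#'   `acceptor_position`, `acceptor_residue`, `acceptor_atom`, `distance`
#'   (A), sorted by distance; attribute `flagged` lists incomplete residues
#'   per chain.
#' @export
detect_interchain_hbonds <- function(alpha, beta, cutoff = 3.5,
                                     include_backbone = TRUE) {
  a_atoms <- if (inherits(alpha, "variable_domain")) alpha$atoms else alpha
  b_atoms <- if (inherits(beta, "variable_domain")) beta$atoms else beta
  stopifnot(cutoff > 0)
  pair_up <- function(don, acc, don_chain, acc_chain) {
    if (nrow(don) == 0 || nrow(acc) == 0) return(NULL)
    dx <- outer(don$x, acc$x, "-"); dy <- outer(don$y, acc$y, "-")
    dz <- outer(don$z, acc$z, "-")
    dist <- sqrt(dx^2 + dy^2 + dz^2)
    hit <- which(dist <= cutoff, arr.ind = TRUE)
    if (nrow(hit) == 0) return(NULL)
    data.frame(
      donor_chain = don_chain,
      donor_position = paste0(don$residue_number, don$insert)[hit[, 1]],
      donor_residue = don$residue_name[hit[, 1]],
      donor_atom = don$atom_name[hit[, 1]],
      acceptor_chain = acc_chain,
      acceptor_position = paste0(acc$residue_number, acc$insert)[hit[, 2]],
      acceptor_residue = acc$residue_name[hit[, 2]],
      acceptor_atom = acc$atom_name[hit[, 2]],
      distance = dist[hit],
      stringsAsFactors = FALSE)
  }
  out <- rbind(
    pair_up(polar_atoms(a_atoms, "donor", include_backbone),
            polar_atoms(b_atoms, "acceptor", include_backbone),
            "alpha", "beta"),
    pair_up(polar_atoms(b_atoms, "donor", include_backbone),
            polar_atoms(a_atoms, "acceptor", include_backbone),
            "beta", "alpha"))
  if (is.null(out))
    out <- data.frame(donor_chain = character(0),
                      donor_position = character(0),
                      donor_residue = character(0),
                      donor_atom = character(0),
                      acceptor_chain = character(0),
                      acceptor_position = character(0),
                      acceptor_residue = character(0),
                      acceptor_atom = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE)
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "flagged") <- list(alpha = flag_incomplete_sidechains(a_atoms),
                               beta = flag_incomplete_sidechains(b_atoms))
  out
}
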