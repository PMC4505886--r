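# Shared fixtures and independent oracles for the test suite.

# Minimal hand-formatted PDB ATOM line (fixed columns), independent of the
# package's own writer.
pdb_atom_line <- function(serial, name, resn, chain, resno, x, y, z,
                          alt = " ", occ = 1, element = "C", insert = " ") {
  name_fmt <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %4s%s%3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name_fmt, alt, resn, chain, resno, insert, x, y, z, occ,
          0, element)
}

write_toy_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# A straight extended C-alpha trace as a variable_domain (3.8 A rise).
straight_domain <- function(n = 30, chain_type = "alpha", rise = 3.8) {
  atoms <- data.frame(atom_name = "CA", residue_name = "ALA",
                      residue_number = seq_len(n), insert = "",
                      chain_id = "A", element = "C",
                      x = rise * seq_len(n), y = sin(seq_len(n)) * 0.3,
                      z = cos(seq_len(n)) * 0.3, altloc = "",
                      occupancy = 1, stringsAsFactors = FALSE)
  extract_variable_domain(atoms, NULL, chain_type)
}

# Pipeline over a planted ensemble (reference first).
pipeline_of <- function(ens, ...) {
  tcr_geometry_pipeline(c(list(ens$reference), ens$complexes),
                        reference_id = "REF0", ...)
}

# Brute-force variance-of-pairwise-distances oracle: per grid point, the
# plain stats::var of all n^2 ordered pair distances (self-pairs included).
variance_field_oracle <- function(positions) {
  n <- length(positions)
  m <- nrow(positions[[1]])
  vapply(seq_len(m), function(i) {
    pts <- t(vapply(positions, function(p) p[i, ], numeric(3)))
    stats::var(as.vector(as.matrix(stats::dist(pts))))
  }, numeric(1))
}

# Best 2-partition under the Ward objective (total within-cluster squared
# deviation from the cluster mean), by exhaustive enumeration.
best_two_partition <- function(X) {
  n <- nrow(X)
  wss <- function(rows) if (length(rows) < 2) 0 else
    sum(sweep(X[rows, , drop = FALSE], 2,
              colMeans(X[rows, , drop = FALSE]))^2)
  best <- NULL; best_val <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    grp <- c(0L, as.integer(intToBits(code))[seq_len(n - 1)])
    val <- wss(which(grp == 0)) + wss(which(grp == 1))
    if (val < best_val) { best_val <- val; best <- grp }
  }
  best + 1L
}

# Adjusted Rand index between two labelings (independent of the package).
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  expected <- si * sj / comb2(sum(tab))
  (sij - expected) / ((si + sj) / 2 - expected)
}

random_euler_triples <- function(n, lim = 180) {
  matrix(stats::runif(3 * n, -lim, lim), ncol = 3)
}
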