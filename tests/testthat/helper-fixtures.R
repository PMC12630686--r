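# Shared fixtures and independent oracles. Oracles here are deliberately
# brute-force / closed-form and never call the code path they check.

# minimal hand-written PDB text (fixed columns), for parser tests
tiny_pdb_lines <- function() c(
  "HEADER    SYNTHETIC TEST",
  "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
  "ATOM      3  C   ALA A   1      10.571   5.719  -4.102  1.00  0.00           C",
  "ATOM      4  O   ALA A   1       9.389   5.931  -4.375  1.00  0.00           O",
  "HETATM    5  C1  LIG B   9       0.000   1.000   2.000  1.00  0.00           C",
  "HETATM    6  O1  LIG B   9       1.500   1.000   2.000  1.00  0.00           O",
  "END")

altloc_pdb_lines <- function() c(
  "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
  "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.60  0.00           C",
  "ATOM      3  CB  ALA A   1       2.000   0.000   0.000  1.00  0.00           C",
  "END")

water_pdb_lines <- function() c(
  "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
  "HETATM    2  O   HOH A   2       3.000   0.000   0.000  1.00  0.00           O",
  "END")

write_lines_tmp <- function(lines, ext = ".pdb") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# exact nearest-neighbour distances by full enumeration (oracle for the
# cell-list implementation)
brute_nn_dist <- function(query, ref) {
  apply(query, 1, function(q)
    sqrt(min(colSums((t(ref) - q)^2))))
}

# independently coded Kirkwood double sum over given beads
brute_kirkwood_rh_nm <- function(beads, bead_radii_A, hydration_nm = 0.3) {
  n <- nrow(beads)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- s + if (i == j) 1 / bead_radii_A[i] else
      1 / sqrt(sum((beads[i, ] - beads[j, ])^2))
  }
  (n^2 / s) / 10 + hydration_nm
}

# random proper rotation (seeded by caller)
random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# count of triangles incident on each undirected mesh edge
edge_incidence <- function(mesh) {
  e <- rbind(mesh$triangles[, c(1, 2)], mesh$triangles[, c(2, 3)],
             mesh$triangles[, c(3, 1)])
  table(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
}

# fast single-atom model with assigned radius
one_atom_model <- function(r = 1.7, at = c(0, 0, 0)) {
  atoms <- data.frame(serial = 1L, name = "C1", element = "C",
                      resname = "SPH", resseq = 1L, chain = "A", altloc = "",
                      occupancy = 1, x = at[1], y = at[2], z = at[3],
                      radius = r, is_ligand = FALSE, is_hydrogen = FALSE)
  structure_model(atoms)
}
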