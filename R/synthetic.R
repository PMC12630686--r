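# Synthetic structures with analytically known geometry: every pipeline
# stage is testable against a closed form, with no external downloads.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

make_atoms <- function(xyz, chain, resname, resseq, is_ligand,
                       name = NULL, element = "C", radius = NA_real_) {
  n <- nrow(xyz)
  data.frame(
    serial = seq_len(n),
    name = name %||% sprintf("C%d", seq_len(n)),
    element = rep_len(element, n),
    resname = rep_len(resname, n),
    resseq = rep_len(resseq, n),
    chain = rep_len(chain, n),
    altloc = "", occupancy = 1,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    radius = rep_len(radius, n),
    is_ligand = rep_len(is_ligand, n),
    is_hydrogen = FALSE,
    stringsAsFactors = FALSE)
}

#' Two pseudo-atoms with analytically known buried areas
#'
#' Two carbon pseudo-atoms on the x axis at the given separation, with
#' explicit radius overrides so the closed-form sphere-pair oracle
#' ([analytic_buried_sasa_sphere_pair()]) controls the geometry exactly.
#' Chains A and B form the two one-atom subunits.
#'
#' @param r1,r2 atom radii in Angstrom.
#' @param separation centre-centre distance in Angstrom.
#' @param probe probe radius carried in the spec (used by the oracle).
#' @return list: `model` (radii pre-assigned), `partition`, `spec`.
#' @export
make_sphere_pair <- function(r1 = 1.7, r2 = 1.7, separation = 4.0,
                             probe = 1.4) {
  stopifnot(r1 > 0, r2 > 0, probe > 0, separation >= 0)
  xyz <- rbind(c(0, 0, 0), c(separation, 0, 0))
  atoms <- make_atoms(xyz, chain = c("A", "B"), resname = "SPH",
                      resseq = c(1, 1), is_ligand = FALSE, name = "C1",
                      radius = c(r1, r2))
  atoms$serial <- 1:2
  model <- structure_model(atoms, label = "sphere_pair")
  list(model = model,
       partition = partition_spec(list(S1 = list(chains = "A"),
                                       S2 = list(chains = "B"))),
       spec = list(r1 = r1, r2 = r2, separation = separation, probe = probe))
}

#' Closed-form buried SASA of a sphere pair
#'
#' With expanded radii R1 = r1 + probe, R2 = r2 + probe and separation d:
#' disjoint (d >= R1+R2) buries nothing; containment (d <= |R1-R2|) buries
#' the smaller sphere fully (its whole 4 pi R^2) and none of the larger;
#' otherwise each sphere loses a cap of height
#' h_i = R_i - (d^2 + R_i^2 - R_j^2) / (2 d), area 2 pi R_i h_i.
#' The degenerate concentric equal-radius case (d = 0, R1 = R2) is treated
#' as full burial of sphere 2 by convention.
#'
#' @param spec list with `r1`, `r2`, `separation`, `probe` (as produced by
#'   [make_sphere_pair()]).
#' @return list with `per_sphere` (length 2) and `total`, in Angstrom^2.
#' @export
analytic_buried_sasa_sphere_pair <- function(spec) {
  R1 <- spec$r1 + spec$probe
  R2 <- spec$r2 + spec$probe
  d <- spec$separation
  if (d >= R1 + R2) {
    per <- c(0, 0)
  } else if (d <= abs(R1 - R2) + 1e-15) {
    small <- if (R1 < R2 || (R1 == R2)) 1 else 2
    # equal radii, concentric: bury sphere 2 by convention
    if (R1 == R2) small <- 2
    per <- c(0, 0)
    per[small] <- 4 * pi * c(R1, R2)[small]^2
  } else {
    h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
    h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
    per <- c(2 * pi * R1 * h1, 2 * pi * R2 * h2)
  }
  list(per_sphere = per, total = sum(per))
}

#' Rigid ligand dimer with known transform and noise
#'
#' Seeded random base coordinates; the second copy is
#' `rotation %*% base + translation` plus isotropic Gaussian noise. Atom
#' names match across copies, so [ligand_pair_rmsd()] applies directly and
#' its result can be cross-checked by direct residual evaluation.
#'
#' @param n_atoms atoms per copy (>= 3).
#' @param rotation 3 x 3 proper rotation; @param translation length-3 vector.
#' @param noise_sigma per-coordinate Gaussian sigma in Angstrom.
#' @param seed RNG seed.
#' @return list: `model`, `base` (n x 3), `spec`.
#' @export
make_rigid_dimer <- function(n_atoms = 30, rotation = diag(3),
                             translation = c(20, 0, 0), noise_sigma = 0,
                             seed = 1) {
  stopifnot(n_atoms >= 3, noise_sigma >= 0)
  with_seed(seed, {
    base <- matrix(runif(3 * n_atoms, -4, 4), ncol = 3)
    copy <- base %*% t(rotation) +
      matrix(translation, n_atoms, 3, byrow = TRUE)
    if (noise_sigma > 0)
      copy <- copy + matrix(rnorm(3 * n_atoms, sd = noise_sigma), ncol = 3)
    atoms <- rbind(
      make_atoms(base, chain = "A", resname = "LIG", resseq = 1,
                 is_ligand = TRUE, radius = 1.7),
      make_atoms(copy, chain = "B", resname = "LIG", resseq = 1,
                 is_ligand = TRUE, radius = 1.7))
    atoms$serial <- seq_len(nrow(atoms))
    list(model = structure_model(atoms, ligand_codes = "LIG",
                                 label = "rigid_dimer"),
         base = base,
         spec = list(n_atoms = n_atoms, rotation = rotation,
                     translation = translation, noise_sigma = noise_sigma,
                     seed = seed))
  })
}

rot_about_x <- function(deg) {
  th <- deg * pi / 180
  matrix(c(1, 0, 0,
           0, cos(th), -sin(th),
           0, sin(th), cos(th)), 3, 3, byrow = TRUE)
}

#' Spiro-like planar ring pair at an exact inter-plane angle
#'
#' Two regular planar rings sharing one vertex at the origin; the second
#' ring's plane is rotated about the x axis by exactly `dihedral_deg`, so
#' [plane_angle()] of the two [best_fit_plane()]s must recover it.
#'
#' @param dihedral_deg target angle in degrees, in [0, 90].
#' @param ring_sizes integer pair, e.g. c(5, 6).
#' @param radius ring circumradius in Angstrom.
#' @return list: `ring1`, `ring2` coordinate matrices, `dihedral_deg`.
#' @export
make_ring_pair <- function(dihedral_deg, ring_sizes = c(5, 6),
                           radius = 1.3) {
  stopifnot(dihedral_deg >= 0, dihedral_deg <= 90, length(ring_sizes) == 2)
  regular_ring <- function(n) {
    th <- 2 * pi * (seq_len(n) - 1) / n
    # vertex 1 at the origin: shift the polygon so it passes through 0
    p <- cbind(radius * cos(th), radius * sin(th), 0)
    sweep(p, 2, p[1, ])
  }
  ring1 <- regular_ring(ring_sizes[1])            # in the z = 0 plane
  ring2 <- regular_ring(ring_sizes[2]) %*% t(rot_about_x(dihedral_deg))
  list(ring1 = ring1, ring2 = ring2, dihedral_deg = dihedral_deg)
}

#' Toy two-domain complex for the end-to-end footprint pipeline
#'
#' Two compact pseudo-domains related by an exact two-fold rotation about z,
#' facing each other across a gap along x, optionally bridged by a
#' symmetry-related 10-atom pseudo-ligand pair at the interface (emulating a
#' glue compound bound between two protomers). Each domain is the
#' `n_per_subunit` lattice points closest to the domain centre (a compact
#' quasi-spherical blob with a well-defined facing surface) plus a small
#' seeded jitter. Chains: A/B protein; ligand residues carried on chains A
#' and B. Radii are pre-assigned (carbon, 1.7 A).
#'
#' @param n_per_subunit protein pseudo-atoms per domain (>= 10).
#' @param gap surface-to-surface gap along x in Angstrom (vdW surfaces of
#'   the closest atoms).
#' @param ligand_at_interface add the bridging pseudo-ligand pair.
#' @param seed RNG seed (jitter only).
#' @param jitter per-coordinate uniform jitter half-width in Angstrom.
#' @return list: `model`, `partition` (subunit P1 = chain A + its ligand,
#'   P2 = chain B + its ligand), `spec`.
#' @export
make_toy_complex <- function(n_per_subunit = 40, gap = 1.0,
                             ligand_at_interface = TRUE, seed = 1,
                             jitter = 0.25) {
  stopifnot(n_per_subunit >= 10)
  with_seed(seed, {
    # compact lattice half-ball: n cubic-lattice points nearest the origin
    # with x <= 0, so the domain presents a flat multi-atom face at x = 0
    # (a real contact patch, as a protein interface would have)
    a <- 2.2
    k <- ceiling((3 * n_per_subunit / (2 * pi))^(1 / 3)) + 2
    g <- as.matrix(expand.grid(x = -k:0, y = -k:k, z = -k:k)) * a
    g <- g[order(rowSums(g^2), g[, 1], g[, 2], g[, 3]), , drop = FALSE]
    blob <- g[seq_len(n_per_subunit), , drop = FALSE]
    blob <- blob + matrix(runif(3 * n_per_subunit, -jitter, jitter),
                          ncol = 3)
    # place so the rightmost vdW surface sits at x = -gap/2
    shift <- -gap / 2 - 1.7 - max(blob[, 1])
    a_xyz <- sweep(blob, 2, c(shift, 0, 0), `+`)
    b_xyz <- a_xyz
    b_xyz[, 1:2] <- -b_xyz[, 1:2]                  # exact C2 about the z axis
    atoms <- rbind(
      make_atoms(a_xyz, chain = "A", resname = "DOM",
                 resseq = seq_len(n_per_subunit), is_ligand = FALSE,
                 radius = 1.7),
      make_atoms(b_xyz, chain = "B", resname = "DOM",
                 resseq = seq_len(n_per_subunit), is_ligand = FALSE,
                 radius = 1.7))
    if (ligand_at_interface) {
      # 5-atom strand per side; bridging for small gaps, attached to its own
      # domain when the gap is wide. Copies related by the same C2.
      lig_off <- max(0.9, gap / 2 - 0.5)
      t <- seq(-2, 2, length.out = 5)
      # gently curved strand (collinear copies would make superposition
      # degenerate)
      lig_a <- cbind(-lig_off + 0.25 * sin(t), t, 1.2 + 0.35 * cos(t))
      lig_b <- lig_a
      lig_b[, 1:2] <- -lig_b[, 1:2]
      atoms <- rbind(
        atoms,
        make_atoms(lig_a, chain = "A", resname = "LIG", resseq = 900,
                   is_ligand = TRUE, radius = 1.7),
        make_atoms(lig_b, chain = "B", resname = "LIG", resseq = 900,
                   is_ligand = TRUE, radius = 1.7))
    }
    atoms$serial <- seq_len(nrow(atoms))
    model <- structure_model(atoms, ligand_codes = "LIG",
                             label = "toy_complex")
    list(model = model,
         partition = partition_spec(list(P1 = list(chains = "A"),
                                         P2 = list(chains = "B"))),
         spec = list(n_per_subunit = n_per_subunit, gap = gap,
                     ligand_at_interface = ligand_at_interface, seed = seed,
                     jitter = jitter))
  })
}
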