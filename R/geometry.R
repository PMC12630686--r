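#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation R and translation t minimizing
#' sum |A_i - (R B_i + t)|^2 under the fixed row correspondence, i.e. moves
#' `coordsB` onto `coordsA`.
#'
#' @param coordsA,coordsB equal-size n x 3 matrices, n >= 3, non-collinear.
#' @return object of class `SuperpositionResult`: `rotation` (3 x 3, det +1),
#'   `translation`, `rmsd`, `n_atoms`.
#' @export
superpose <- function(coordsA, coordsB) {
  coordsA <- as.matrix(coordsA); coordsB <- as.matrix(coordsB)
  if (!all(dim(coordsA) == dim(coordsB)))
    stop("coordinate sets differ in size")
  n <- nrow(coordsA)
  if (n < 3) stop("degenerate: need at least 3 points")
  ca <- colMeans(coordsA); cb <- colMeans(coordsB)
  A <- sweep(coordsA, 2, ca); B <- sweep(coordsB, 2, cb)
  if (min(svd(A)$d[2], svd(B)$d[2]) < 1e-10)
    stop("degenerate: points are collinear")
  H <- crossprod(B, A)            # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t <- ca - as.vector(R %*% cb)
  moved <- transform_coords(coordsB, R, t)
  rmsd <- sqrt(mean(rowSums((coordsA - moved)^2)))
  structure(list(rotation = R, translation = t, rmsd = rmsd, n_atoms = n),
            class = "SuperpositionResult")
}

#' Apply a rigid transform to coordinates
#' @param xyz n x 3 matrix.
#' @param rotation 3 x 3 matrix; @param translation length-3 vector.
#' @export
transform_coords <- function(xyz, rotation, translation) {
  sweep(as.matrix(xyz) %*% t(rotation), 2, -translation)
}

#' All-atom RMSD between the two copies of a ligand
#'
#' The model must contain exactly two copies of the ligand residue; atoms are
#' put in correspondence by atom name (all modelled heavy atoms), the copies
#' are superposed, and the residual RMSD is reported.
#'
#' @param model `StructureModel`.
#' @param ligand_code ligand residue code; default: the model's single
#'   ligand code.
#' @return a `SuperpositionResult` with a `correspondence` atom-name vector.
#' @export
ligand_pair_rmsd <- function(model, ligand_code = NULL) {
  a <- model$atoms
  if (is.null(ligand_code)) {
    codes <- unique(a$resname[a$is_ligand])
    if (length(codes) != 1)
      stop("ligand_code required (model has ", length(codes),
           " ligand codes)")
    ligand_code <- codes
  }
  lig <- a[a$resname == ligand_code, , drop = FALSE]
  copy_id <- paste(lig$chain, lig$resseq, sep = "/")
  copies <- unique(copy_id)
  if (length(copies) != 2)
    stop("expected exactly 2 copies of '", ligand_code, "', found ",
         length(copies))
  c1 <- lig[copy_id == copies[1], , drop = FALSE]
  c2 <- lig[copy_id == copies[2], , drop = FALSE]
  only1 <- setdiff(c1$name, c2$name); only2 <- setdiff(c2$name, c1$name)
  if (length(only1) || length(only2))
    stop("atom-name mismatch between ligand copies: ",
         paste(c(paste0(copies[1], ":", only1),
                 paste0(copies[2], ":", only2)), collapse = ", "))
  c2 <- c2[match(c1$name, c2$name), , drop = FALSE]
  res <- superpose(as.matrix(c1[, c("x", "y", "z")]),
                   as.matrix(c2[, c("x", "y", "z")]))
  res$correspondence <- c1$name
  res
}

#' Best-fit plane through a point set
#'
#' Plane through the centroid minimizing squared orthogonal distances; the
#' normal is the smallest principal direction.
#'
#' @param xyz n x 3 matrix, n >= 3, non-collinear.
#' @return object of class `PlaneFit`: `centroid`, unit `normal`,
#'   `planarity_rms` (Angstrom).
#' @export
best_fit_plane <- function(xyz) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 3) stop("degenerate: need at least 3 points")
  ctr <- colMeans(xyz)
  X <- sweep(xyz, 2, ctr)
  s <- svd(X)
  if (s$d[2] < 1e-10) stop("degenerate: points are collinear")
  normal <- s$v[, 3]
  normal <- normal / sqrt(sum(normal^2))
  structure(list(centroid = ctr, normal = normal,
                 planarity_rms = sqrt(mean((X %*% normal)^2))),
            class = "PlaneFit")
}

#' Angle between two fitted planes
#'
#' Folded to [0, 90] degrees; insensitive to normal sign.
#'
#' @param a,b `PlaneFit` objects.
#' @return angle in degrees.
#' @export
plane_angle <- function(a, b) {
  ca <- abs(sum(a$normal * b$normal))
  acos(min(1, ca)) * 180 / pi
}

# Donor/acceptor typing for standard residues, by atom name. Backbone N is a
# donor and backbone O an acceptor for every residue; sidechain roles below.
DONOR_SIDECHAIN <- list(
  SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG",
  ASN = "ND2", GLN = "NE2", LYS = "NZ",
  ARG = c("NE", "NH1", "NH2"), TRP = "NE1", HIS = c("ND1", "NE2"))
ACCEPTOR_SIDECHAIN <- list(
  SER = "OG", THR = "OG1", TYR = "OH",
  ASN = "OD1", GLN = "OE1", ASP = c("OD1", "OD2"),
  GLU = c("OE1", "OE2"), HIS = c("ND1", "NE2"), MET = "SD")

atom_roles <- function(atoms) {
  # ligand atoms: any N/O is both donor and acceptor (no chemistry
  # perception -- documented heuristic); protein atoms by the tables above.
  don <- acc <- logical(nrow(atoms))
  lig <- atoms$is_ligand
  don[lig] <- atoms$element[lig] %in% c("N", "O")
  acc[lig] <- atoms$element[lig] %in% c("N", "O")
  pro <- !lig
  don[pro] <- atoms$name[pro] == "N"
  acc[pro] <- atoms$name[pro] %in% c("O", "OXT")
  for (res in names(DONOR_SIDECHAIN)) {
    hit <- pro & atoms$resname == res & atoms$name %in% DONOR_SIDECHAIN[[res]]
    don[hit] <- TRUE
  }
  for (res in names(ACCEPTOR_SIDECHAIN)) {
    hit <- pro & atoms$resname == res &
      atoms$name %in% ACCEPTOR_SIDECHAIN[[res]]
    acc[hit] <- TRUE
  }
  list(donor = don, acceptor = acc)
}

#' Contact-detection distance criteria
#'
#' Heavy-atom distance bands (no angle terms: deposited models carry no
#' hydrogens). Canonical hydrogen bond: donor-acceptor distance in
#' (min, canonical]; weak hydrogen bond: (canonical, weak]; C-H...O contact:
#' carbon-oxygen distance <= ch_o.
#' @param canonical,weak,ch_o,min_dist band edges in Angstrom.
#' @export
contact_criteria <- function(canonical = 3.5, weak = 4.0, ch_o = 3.7,
                             min_dist = 2.2) {
  structure(list(canonical = canonical, weak = weak, ch_o = ch_o,
                 min_dist = min_dist), class = "ContactCriteria")
}

#' Geometric polar contacts between two selections
#'
#' Enumerates donor/acceptor pairs across the two selections and classifies
#' them by heavy-atom distance into canonical hydrogen bonds, weak hydrogen
#' bonds, and non-classical C-H...O contacts. Each unordered atom pair is
#' reported once. Records are labelled cis/trans by the chain of the
#' non-ligand partner (or of the second-selection atom) relative to
#' `cis_chains`.
#'
#' @param model `StructureModel`.
#' @param sel1,sel2 subunit specs accepted by [select_subunit()], or logical
#'   masks over the atom table.
#' @param criteria [contact_criteria()].
#' @param cis_chains chains counted as the cis protomer (optional).
#' @return data.frame of class `ContactTable`, one row per contact: kind,
#'   donor/acceptor identity, distance, cis_trans.
#' @export
find_polar_contacts <- function(model, sel1, sel2,
                                criteria = contact_criteria(),
                                cis_chains = NULL) {
  a <- model$atoms
  as_mask <- function(sel) {
    if (is.logical(sel)) return(sel)
    if (is.character(sel)) sel <- list(chains = sel)
    subunit_mask(model, sel)
  }
  m1 <- as_mask(sel1); m2 <- as_mask(sel2)
  if (!any(m1) || !any(m2)) stop("empty selection")
  i1 <- which(m1); i2 <- which(m2)
  roles <- atom_roles(a)

  # all cross pairs within the widest cutoff
  xyz <- coords(model)
  cut <- max(criteria$weak, criteria$ch_o)
  pairs <- expand.grid(i = i1, j = i2)
  pairs <- pairs[pairs$i != pairs$j, , drop = FALSE]
  d <- sqrt(rowSums((xyz[pairs$i, , drop = FALSE] -
                       xyz[pairs$j, , drop = FALSE])^2))
  keep <- d <= cut & d >= criteria$min_dist
  pairs <- pairs[keep, , drop = FALSE]; d <- d[keep]
  if (nrow(pairs) == 0) return(empty_contact_table())

  rec <- list(); k <- 0
  seen <- character()
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]; j <- pairs$j[r]; dij <- d[r]
    pk <- paste(min(i, j), max(i, j))
    if (pk %in% seen) next
    kind <- NA_character_; donor <- NA_integer_; acceptor <- NA_integer_
    da <- (roles$donor[i] && roles$acceptor[j])
    ad <- (roles$donor[j] && roles$acceptor[i])
    if ((da || ad) && dij <= criteria$weak) {
      kind <- if (dij <= criteria$canonical) "canonical_hbond" else
        "weak_hbond"
      if (da) { donor <- i; acceptor <- j } else { donor <- j; acceptor <- i }
    } else if (dij <= criteria$ch_o &&
               ((a$element[i] == "C" && a$element[j] == "O") ||
                (a$element[j] == "C" && a$element[i] == "O"))) {
      kind <- "ch_o_contact"
      if (a$element[i] == "C") { donor <- i; acceptor <- j }
      else { donor <- j; acceptor <- i }
    }
    if (is.na(kind)) next
    seen <- c(seen, pk)
    ref <- if (!a$is_ligand[acceptor]) acceptor else donor
    ct <- if (is.null(cis_chains)) NA_character_ else
      if (a$chain[ref] %in% cis_chains) "cis" else "trans"
    k <- k + 1
    rec[[k]] <- data.frame(
      kind = kind,
      donor_chain = a$chain[donor], donor_res = a$resname[donor],
      donor_seq = a$resseq[donor], donor_atom = a$name[donor],
      acceptor_chain = a$chain[acceptor], acceptor_res = a$resname[acceptor],
      acceptor_seq = a$resseq[acceptor], acceptor_atom = a$name[acceptor],
      distance = dij, cis_trans = ct, stringsAsFactors = FALSE)
  }
  if (k == 0) return(empty_contact_table())
  out <- do.call(rbind, rec)
  out <- out[order(out$distance), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ContactTable", "data.frame")
  out
}

empty_contact_table <- function() {
  out <- data.frame(kind = character(), donor_chain = character(),
                    donor_res = character(), donor_seq = integer(),
                    donor_atom = character(), acceptor_chain = character(),
                    acceptor_res = character(), acceptor_seq = integer(),
                    acceptor_atom = character(), distance = numeric(),
                    cis_trans = character(), stringsAsFactors = FALSE)
  class(out) <- c("ContactTable", "data.frame")
  out
}

#' Superpose one model onto another by matched selections
#'
#' Superposes on a named-atom correspondence (default C-alpha) between two
#' residue selections and returns the transformed whole of `modelB` for
#' downstream distance queries.
#'
#' @param modelA,modelB `StructureModel`s.
#' @param selA,selB subunit specs (see [select_subunit()]).
#' @param atom_name atom used for the correspondence (default "CA").
#' @return list: `superposition` (a `SuperpositionResult`) and `transformed`
#'   (modelB moved onto modelA's frame).
#' @export
superpose_by_selection <- function(modelA, modelB, selA, selB,
                                   atom_name = "CA") {
  pick <- function(model, sel) {
    sub <- select_subunit(model, sel)
    a <- sub$atoms[sub$atoms$name == atom_name, , drop = FALSE]
    a[order(a$chain, a$resseq), , drop = FALSE]
  }
  aA <- pick(modelA, selA); aB <- pick(modelB, selB)
  if (nrow(aA) != nrow(aB))
    stop("unequal correspondence: ", nrow(aA), " vs ", nrow(aB), " '",
         atom_name, "' atoms; unmatched residues: ",
         paste(head(c(
           setdiff(paste0(aA$chain, aA$resseq), paste0(aB$chain, aB$resseq)),
           setdiff(paste0(aB$chain, aB$resseq), paste0(aA$chain, aA$resseq))),
           10), collapse = ","))
  sp <- superpose(as.matrix(aA[, c("x", "y", "z")]),
                  as.matrix(aB[, c("x", "y", "z")]))
  moved <- modelB
  new_xyz <- transform_coords(coords(modelB), sp$rotation, sp$translation)
  moved$atoms$x <- new_xyz[, 1]
  moved$atoms$y <- new_xyz[, 2]
  moved$atoms$z <- new_xyz[, 3]
  list(superposition = sp, transformed = moved)
}

#' Hydrodynamic radius from coordinates (Kirkwood bead model)
#'
#' Coarse-grains the structure to one bead per protein residue (at the
#' residue's heavy-atom centroid) plus one bead per ligand atom, and applies
#' the Kirkwood double-sum approximation
#' \deqn{1/R_0 = (1/N^2) (\sum_i 1/a_i + \sum_{i \ne j} 1/r_{ij})}
#' followed by a declared hydration-shell increment:
#' \eqn{R_h = R_0 + \delta}. A single bead returns its radius plus the
#' increment.
#'
#' @param model `StructureModel` with radii assigned.
#' @param method only `"kirkwood_beads"`.
#' @param bead_radius residue-bead radius in Angstrom (default 3.0).
#' @param hydration hydration increment in nm added to the final radius
#'   (default 0.3 nm).
#' @return object of class `RhEstimate`: `rh` (nm), `method`, `n_beads`,
#'   `hydration_nm`.
#' @export
predict_rh <- function(model, method = "kirkwood_beads", bead_radius = 3.0,
                       hydration = 0.3) {
  method <- match.arg(method, "kirkwood_beads")
  require_radii(model)
  a <- model$atoms
  pro <- a[!a$is_ligand, , drop = FALSE]
  beads <- NULL; brad <- NULL
  if (nrow(pro) > 0) {
    key <- paste(pro$chain, pro$resseq, sep = "/")
    cx <- rowsum(pro$x, key); cy <- rowsum(pro$y, key)
    cz <- rowsum(pro$z, key); cnt <- rowsum(rep(1, nrow(pro)), key)
    beads <- cbind(cx / cnt, cy / cnt, cz / cnt)
    brad <- rep(bead_radius, nrow(beads))
  }
  lig <- a[a$is_ligand, , drop = FALSE]
  if (nrow(lig) > 0) {
    beads <- rbind(beads, as.matrix(lig[, c("x", "y", "z")]))
    brad <- c(brad, lig$radius)
  }
  n <- nrow(beads)
  rh_ang <- if (n == 1) brad[1] else {
    dmat <- as.matrix(stats::dist(beads))
    inv <- 1 / dmat
    diag(inv) <- 1 / brad
    n^2 / sum(inv)
  }
  structure(list(rh = rh_ang / 10 + hydration, method = method,
                 n_beads = n, hydration_nm = hydration,
                 bead_radius_A = bead_radius),
            class = "RhEstimate")
}
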