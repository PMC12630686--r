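test_that("superposition recovers rigid transforms and is symmetric", {
  set.seed(12)
  A <- matrix(runif(3 * 30, -5, 5), ncol = 3)
  sp0 <- superpose(A, A)
  expect_lt(sp0$rmsd, 1e-9)
  expect_equal(sp0$rotation, diag(3), tolerance = 1e-9)

  R <- random_rotation(); tr <- c(3, -8, 1)
  B <- transform_coords(A, R, tr)
  sp <- superpose(A, B)
  expect_lt(sp$rmsd, 1e-9)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)

  # noisy case: rmsd symmetric and reproduced by direct residual evaluation
  Bn <- B + matrix(rnorm(length(B), sd = 0.1), ncol = 3)
  s1 <- superpose(A, Bn); s2 <- superpose(Bn, A)
  expect_equal(s1$rmsd, s2$rmsd, tolerance = 1e-9)
  direct <- sqrt(mean(rowSums(
    (A - transform_coords(Bn, s1$rotation, s1$translation))^2)))
  expect_equal(s1$rmsd, direct, tolerance = 1e-9)
  # invariance under a joint rigid transform
  R2 <- random_rotation()
  s3 <- superpose(transform_coords(A, R2, c(1, 2, 3)),
                  transform_coords(Bn, R2, c(1, 2, 3)))
  expect_equal(s3$rmsd, s1$rmsd, tolerance = 1e-9)

  expect_error(superpose(A[1:2, ], A[1:2, ]), "at least 3")
  L <- cbind(1:5, 0, 0)
  expect_error(superpose(L, L), "collinear")
})

test_that("ligand-pair RMSD: correspondence by name, with precise errors", {
  rd0 <- make_rigid_dimer(20, random_rotation(), c(12, 0, 5),
                          noise_sigma = 0, seed = 3)
  expect_lt(ligand_pair_rmsd(rd0$model, "LIG")$rmsd, 1e-9)

  # shuffled atom order in one copy must not matter (name correspondence)
  m <- rd0$model
  idx_b <- which(m$atoms$chain == "B")
  set.seed(1); m$atoms[idx_b, ] <- m$atoms[sample(idx_b), ]
  expect_lt(ligand_pair_rmsd(m, "LIG")$rmsd, 1e-9)

  # missing atom named in the error
  m2 <- rd0$model
  m2$atoms <- m2$atoms[!(m2$atoms$chain == "B" & m2$atoms$name == "C7"), ]
  expect_error(ligand_pair_rmsd(m2, "LIG"), "C7")

  # wrong copy count
  m3 <- rd0$model
  m3$atoms <- m3$atoms[m3$atoms$chain == "A", ]
  expect_error(ligand_pair_rmsd(m3, "LIG"), "exactly 2")
})

test_that("plane fitting and inter-plane angles", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  f <- best_fit_plane(sq)
  expect_equal(f$planarity_rms, 0, tolerance = 1e-12)
  expect_equal(abs(f$normal), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(sqrt(sum(f$normal^2)), 1, tolerance = 1e-12)
  # 3 points are exactly planar
  expect_equal(best_fit_plane(sq[1:3, ])$planarity_rms, 0, tolerance = 1e-12)
  expect_error(best_fit_plane(cbind(0:4, 0, 0)), "collinear")

  # puckered ring: out-of-plane displacement along the cos(2*theta) mode,
  # which is orthogonal to the plane's degrees of freedom (constant + tilt),
  # so the best-fit plane stays z = 0 and rms equals the amplitude exactly
  eps <- 0.07
  th <- 2 * pi * (0:4) / 5
  ring <- cbind(1.3 * cos(th), 1.3 * sin(th), eps * sqrt(2) * cos(2 * th))
  fr <- best_fit_plane(ring)
  expect_equal(fr$planarity_rms, eps, tolerance = 1e-9)

  # angle properties: identity, fold to [0,90], sign-flip invariance
  expect_equal(plane_angle(f, f), 0)
  g <- f; g$normal <- -g$normal
  expect_equal(plane_angle(f, g), 0)
  for (ang in c(0, 15, 45, 81, 90)) {
    rp <- make_ring_pair(ang)
    got <- plane_angle(best_fit_plane(rp$ring1), best_fit_plane(rp$ring2))
    expect_equal(got, ang, tolerance = 1e-6)
  }
})

test_that("polar contacts: bands, typing, symmetry and monotonicity", {
  mk <- function(d, el = c("N", "O"), resname = "LIG") {
    atoms <- data.frame(serial = 1:2, name = paste0(el, "9"), element = el,
                        resname = resname, resseq = 1:2,
                        chain = c("A", "B"), altloc = "", occupancy = 1,
                        x = c(0, d), y = 0, z = 0, radius = 1.6,
                        is_ligand = TRUE, is_hydrogen = FALSE)
    structure_model(atoms, ligand_codes = resname)
  }
  # constructed N...O at 2.9 A -> exactly one canonical H-bond
  ct <- find_polar_contacts(mk(2.9), "A", "B")
  expect_equal(nrow(ct), 1)
  expect_equal(ct$kind, "canonical_hbond")
  expect_equal(ct$distance, 2.9)
  # 3.8 A -> weak; 5.0 A -> nothing
  expect_equal(find_polar_contacts(mk(3.8), "A", "B")$kind, "weak_hbond")
  expect_equal(nrow(find_polar_contacts(mk(5.0), "A", "B")), 0)
  # C...O at 3.4 -> non-classical contact; C...C never typed
  expect_equal(find_polar_contacts(mk(3.4, c("C", "O")), "A", "B")$kind,
               "ch_o_contact")
  expect_equal(nrow(find_polar_contacts(mk(3.4, c("C", "C")), "A", "B")), 0)
  # symmetric in selection order
  c1 <- find_polar_contacts(mk(2.9), "A", "B")
  c2 <- find_polar_contacts(mk(2.9), "B", "A")
  expect_equal(c1$distance, c2$distance)
  expect_equal(c1$kind, c2$kind)
  # counts monotone in cutoffs
  m <- mk(3.6)
  n_tight <- nrow(find_polar_contacts(m, "A", "B",
                                      contact_criteria(canonical = 3.0,
                                                       weak = 3.5,
                                                       ch_o = 3.0)))
  n_wide <- nrow(find_polar_contacts(m, "A", "B",
                                     contact_criteria(canonical = 3.5,
                                                      weak = 4.0,
                                                      ch_o = 3.7)))
  expect_lte(n_tight, n_wide)
  expect_error(find_polar_contacts(mk(2.9), "Z", "B"), "empty selection")
})

test_that("protein donor/acceptor typing and cis/trans labelling", {
  # trans-chain TRP NE1 (donor) to cis-chain ligand O (acceptor) at 3.0 A
  atoms <- data.frame(
    serial = 1:3,
    name = c("NE1", "O1", "CZ2"), element = c("N", "O", "C"),
    resname = c("TRP", "MGD", "TRP"), resseq = c(400, 901, 400),
    chain = c("B", "A", "B"), altloc = "", occupancy = 1,
    x = c(0, 3.0, 1.0), y = c(0, 0, 2.0), z = 0, radius = 1.6,
    is_ligand = c(FALSE, TRUE, FALSE), is_hydrogen = FALSE,
    stringsAsFactors = FALSE)
  m <- structure_model(atoms, ligand_codes = "MGD")
  ct <- find_polar_contacts(m, "A", "B", cis_chains = "A")
  hb <- ct[ct$kind == "canonical_hbond", ]
  expect_equal(nrow(hb), 1)
  expect_equal(hb$donor_atom, "NE1")
  expect_equal(hb$acceptor_atom, "O1")
  expect_equal(hb$cis_trans, "trans")   # protein partner is on chain B
  # backbone carbonyl C is not a donor/acceptor; CZ2...O1 is a C-H...O
  cho <- ct[ct$kind == "ch_o_contact", ]
  expect_equal(nrow(cho), 1)
  expect_equal(cho$donor_atom, "CZ2")
})

test_that("superpose_by_selection returns transform and moved model", {
  set.seed(5)
  n <- 15
  xyz <- matrix(runif(3 * n, -9, 9), ncol = 3)
  atoms <- one_atom_model()$atoms[rep(1, n), ]
  atoms$serial <- seq_len(n); atoms$resseq <- seq_len(n)
  atoms$name <- "CA"; atoms$resname <- "GLY"
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  mA <- structure_model(atoms)
  R <- random_rotation(); tr <- c(4, 4, -2)
  mB <- mA
  moved <- transform_coords(xyz, R, tr)
  mB$atoms$x <- moved[, 1]; mB$atoms$y <- moved[, 2]
  mB$atoms$z <- moved[, 3]
  res <- superpose_by_selection(mA, mB, list(chains = "A"),
                                list(chains = "A"))
  expect_lt(res$superposition$rmsd, 1e-9)
  expect_lt(max(abs(coords(res$transformed) - coords(mA))), 1e-9)
  # unequal correspondences are rejected with the offender listed
  mC <- mB
  mC$atoms <- mC$atoms[-1, ]
  expect_error(superpose_by_selection(mA, mC, list(chains = "A"),
                                      list(chains = "A")),
               "unequal correspondence")
})

test_that("Kirkwood Rh: brute-force equality, invariances, monotonicity", {
  set.seed(21)
  for (rep in 1:3) {
    n <- sample(8:20, 1)
    beads <- matrix(runif(3 * n, -8, 8), ncol = 3)
    atoms <- one_atom_model()$atoms[rep(1, n), ]
    atoms$serial <- seq_len(n); atoms$resseq <- seq_len(n)
    atoms$x <- beads[, 1]; atoms$y <- beads[, 2]; atoms$z <- beads[, 3]
    m <- structure_model(atoms)
    got <- predict_rh(m)
    want <- brute_kirkwood_rh_nm(beads, rep(3.0, n))
    expect_equal(got$rh, want, tolerance = 1e-9)
    # rigid-transform invariance
    R <- random_rotation()
    m2 <- m
    xyz <- transform_coords(beads, R, c(7, -1, 2))
    m2$atoms$x <- xyz[, 1]; m2$atoms$y <- xyz[, 2]; m2$atoms$z <- xyz[, 3]
    expect_equal(predict_rh(m2)$rh, got$rh, tolerance = 1e-9)
    # moving beads apart increases Rh
    m3 <- m
    m3$atoms$x <- m3$atoms$x * 1.5
    m3$atoms$y <- m3$atoms$y * 1.5
    m3$atoms$z <- m3$atoms$z * 1.5
    expect_gt(predict_rh(m3)$rh, got$rh)
  }
  # single bead: its radius plus the hydration increment
  m1 <- one_atom_model(2.0)
  m1$atoms$is_ligand <- TRUE     # one ligand-atom bead of radius 2 A
  expect_equal(predict_rh(m1)$rh, 0.2 + 0.3, tolerance = 1e-12)
})
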