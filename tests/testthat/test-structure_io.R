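test_that("PDB parsing filters waters/hydrogens and keeps best altloc", {
  f <- write_lines_tmp(tiny_pdb_lines())
  m <- load_structure(f, "pdb", ligand_codes = "LIG")
  expect_s3_class(m, "StructureModel")
  expect_equal(n_atoms(m), 6)
  expect_setequal(m$chains, c("A", "B"))
  expect_equal(sum(m$atoms$is_ligand), 2)
  expect_true(all(is.na(m$atoms$radius)))

  fa <- write_lines_tmp(altloc_pdb_lines())
  ma <- load_structure(fa, "pdb")
  expect_equal(n_atoms(ma), 2)          # one CA conformer + CB
  expect_equal(ma$atoms$x[ma$atoms$name == "CA"], 1.0)  # occupancy 0.6 wins

  fw <- write_lines_tmp(water_pdb_lines())
  expect_error(load_structure(fw, "pdb"), "empty model")
  expect_error(load_structure(tempfile(), "pdb"), "not found")
})

test_that("ligand identity falls back to HETATM when no codes given", {
  f <- write_lines_tmp(tiny_pdb_lines())
  m <- load_structure(f, "pdb")
  expect_equal(sum(m$atoms$is_ligand), 2)
  expect_equal(unique(m$atoms$resname[m$atoms$is_ligand]), "LIG")
})

test_that("write/load round trip is the identity (pdb and mmcif)", {
  tc <- make_toy_complex(20, 2.0, seed = 5)
  for (fmt in c("pdb", "mmcif")) {
    f <- tempfile(fileext = if (fmt == "pdb") ".pdb" else ".cif")
    write_structure(tc$model, f, fmt)
    m2 <- load_structure(f, fmt, ligand_codes = "LIG")
    expect_equal(n_atoms(m2), n_atoms(tc$model))
    expect_equal(m2$atoms$name, tc$model$atoms$name)
    expect_equal(m2$atoms$chain, tc$model$atoms$chain)
    expect_equal(m2$atoms$resseq, tc$model$atoms$resseq)
    expect_equal(m2$atoms$is_ligand, tc$model$atoms$is_ligand)
    expect_lt(max(abs(coords(m2) - coords(tc$model))), 1e-3)
    # ligand emitted as HETATM in PDB
    if (fmt == "pdb")
      expect_equal(sum(grepl("^HETATM", readLines(f))),
                   sum(tc$model$atoms$is_ligand))
  }
  expect_error(write_structure(
    structure_model(tc$model$atoms[0, ]), tempfile(), "pdb"), "empty")
})

test_that("mmCIF parser handles label-only naming and quoting", {
  cif <- c("data_x", "loop_", "_atom_site.group_PDB", "_atom_site.id",
           "_atom_site.type_symbol", "_atom_site.label_atom_id",
           "_atom_site.label_alt_id", "_atom_site.label_comp_id",
           "_atom_site.label_asym_id", "_atom_site.label_seq_id",
           "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
           "_atom_site.occupancy",
           "ATOM 1 C CA . ALA A 1 0.0 0.0 0.0 1.00",
           "ATOM 2 C \"C1'\" . ALA A 1 1.5 0.0 0.0 1.00", "#")
  m <- load_structure(write_lines_tmp(cif, ".cif"), "mmcif")
  expect_equal(n_atoms(m), 2)
  expect_equal(m$atoms$chain, c("A", "A"))   # label fallback
  expect_equal(m$atoms$name[2], "C1'")
})

test_that("radius assignment is table-driven, idempotent, with fallback", {
  f <- write_lines_tmp(tiny_pdb_lines())
  m <- load_structure(f, "pdb", ligand_codes = "LIG")
  m2 <- assign_radii(m)
  expect_equal(m2$atoms$radius[m2$atoms$element == "C"][1], 1.70)
  expect_equal(m2$atoms$radius[m2$atoms$element == "N"][1], 1.55)
  expect_equal(m2$atoms$radius[m2$atoms$element == "O"][1], 1.52)
  expect_identical(assign_radii(m2)$atoms$radius, m2$atoms$radius)

  mx <- m
  mx$atoms$element[1] <- "XX"
  expect_warning(mx2 <- assign_radii(mx), "unknown element")
  expect_equal(mx2$atoms$radius[1], 1.70)
  expect_error(radius_table(default_radius = 5), "radii")
  expect_error(assign_radii(structure_model(m$atoms[0, ])), "empty")
})

test_that("selection preserves order/flags; partition counts are additive", {
  tc <- make_toy_complex(25, 2.0, seed = 2)
  m <- tc$model
  s1 <- select_subunit(m, list(chains = "A"))
  s2 <- select_subunit(m, list(chains = "B"))
  expect_equal(n_atoms(s1) + n_atoms(s2), n_atoms(m))
  expect_identical(select_subunit(m, list(chains = c("A", "B")))$atoms,
                   m$atoms)
  expect_equal(sum(s1$atoms$is_ligand), 5)
  expect_false(is.unsorted(match(s1$atoms$serial, m$atoms$serial)))
  expect_error(select_subunit(m, list(chains = "Z")), "empty selection")
  # residue-range restriction
  s3 <- select_subunit(m, list(chains = "A",
                               residues = list(A = c(900, 900))))
  expect_true(all(s3$atoms$resseq[s3$atoms$chain == "A" &
                                    s3$atoms$is_ligand] == 900))
  # overlapping partitions are rejected
  bad <- partition_spec(list(P1 = list(chains = "A"),
                             P2 = list(chains = c("A", "B"))))
  expect_error(buried_sasa(assign_radii(m), bad), "overlap")
})
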