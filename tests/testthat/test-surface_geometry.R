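test_that("SASA: isolated atoms are exact; occlusion follows the oracle", {
  p <- surface_params()
  m <- one_atom_model(1.7)
  s <- compute_sasa(m, p)
  expect_equal(s$total, 4 * pi * 3.1^2, tolerance = 1e-12)
  expect_equal(s$total, sum(s$per_atom_area))

  # beyond mutual reach: sum of isolated areas, exactly
  far <- make_sphere_pair(1.7, 1.5, separation = 50)
  sf <- compute_sasa(far$model, p)
  expect_equal(sf$total, 4 * pi * (3.1^2 + 2.9^2), tolerance = 1e-12)

  # spec example: expanded radii 2.0 at separation 2.0 -> caps of height 1
  sp <- make_sphere_pair(0.6, 0.6, separation = 2.0)
  st <- compute_sasa(sp$model, p)
  expect_equal(st$total, 2 * (4 * pi * 4 - 2 * pi * 2 * 1), tolerance = 0.02)

  # unassigned radii rejected
  bad <- sp$model; bad$atoms$radius <- NA_real_
  expect_error(compute_sasa(bad, p), "radii unassigned")
})

test_that("SASA quadrature is deterministic and resolution-bounded", {
  p <- surface_params()
  sp <- make_sphere_pair(2.0, 2.0, separation = 5.0)
  s1 <- compute_sasa(sp$model, p)
  s2 <- compute_sasa(sp$model, p)
  expect_identical(s1$per_atom_area, s2$per_atom_area)

  # the quadrature converges to the closed form: at 16x the default point
  # density even the near-tangent caps are within 2% of the oracle
  dense <- surface_params(sasa_points = 15360)
  for (r in c(1.5, 2.0, 3.0)) {
    for (d in seq(2 * r, 2 * (r + 1.4), length.out = 10)) {
      spd <- make_sphere_pair(r, r, d)
      an <- analytic_buried_sasa_sphere_pair(spd$spec)$total
      got <- buried_sasa(spd$model, spd$partition, dense)$total
      if (an > 0) expect_lt(abs(got / an - 1), 0.02) else
        expect_equal(got, 0)
    }
  }
})

test_that("buried SASA is monotone as spheres approach", {
  p <- surface_params()
  prev <- -Inf
  for (d in rev(seq(0.5, 7.5, by = 0.5))) {
    spd <- make_sphere_pair(2.0, 2.0, d)
    tot <- buried_sasa(spd$model, spd$partition, p)$total
    expect_gte(tot + 1e-9, prev)
    prev <- tot
  }
})

test_that("SES mesh: closed, area-accurate, attribution and areas behave", {
  p <- surface_params()
  m <- one_atom_model(1.7)
  mesh <- compute_ses_mesh(m, p)
  # closed orientable single body: every edge on exactly 2 triangles
  expect_true(all(edge_incidence(mesh) == 2))
  expect_equal(mesh_area(mesh), 4 * pi * 1.7^2, tolerance = 0.02)
  # vertex areas conserve total area
  expect_equal(sum(mesh$vertex_area), mesh_area(mesh), tolerance = 1e-9)
  # all vertices attributed to the only atom
  expect_true(all(mesh$vertex_atom == 1L))
  # dimer in contact: complex area < sum of subunit areas
  sp <- make_sphere_pair(2.0, 2.0, separation = 3.0)
  a_complex <- mesh_area(compute_ses_mesh(sp$model, p, attribute = FALSE))
  a_sub <- 2 * mesh_area(compute_ses_mesh(
    select_subunit(sp$model, "A"), p, attribute = FALSE))
  expect_lt(a_complex, a_sub)
  # too-coarse grid rejected
  small <- one_atom_model(0.4)
  expect_error(compute_ses_mesh(small, surface_params(grid_spacing = 0.5)),
               "grid too coarse")
})

test_that("SES meshing is deterministic", {
  p <- surface_params()
  sp <- make_sphere_pair(2.0, 1.5, separation = 3.0)
  m1 <- compute_ses_mesh(sp$model, p)
  m2 <- compute_ses_mesh(sp$model, p)
  expect_identical(m1$vertices, m2$vertices)
  expect_identical(m1$triangles, m2$triangles)
  expect_identical(m1$vertex_area, m2$vertex_area)
})

test_that("vertex areas: single-face mesh and degenerate triangles", {
  tri <- structure(list(
    vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
    triangles = matrix(c(1L, 2L, 3L), 1)), class = "TriangleMesh")
  va <- vertex_areas(tri)
  expect_equal(va, rep(1 / 6, 3))
  # zero-area triangle tolerated, contributes 0
  degen <- structure(list(
    vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
    triangles = matrix(c(1L, 2L, 3L), 1)), class = "TriangleMesh")
  expect_equal(vertex_areas(degen), rep(0, 3))
})

test_that("vertex-atom attribution uses surface distance with serial ties", {
  # unequal radii: point nearer (in surface distance) to the big atom
  atoms <- rbind(one_atom_model(2.5, c(0, 0, 0))$atoms,
                 one_atom_model(1.0, c(6, 0, 0))$atoms)
  atoms$serial <- 1:2
  m <- structure_model(atoms)
  v <- rbind(c(3.4, 0, 0),   # surface dist: 0.9 to atom1, 1.6 to atom2
             c(3.75, 0, 0))  # equidistant (1.25 each) -> lower serial
  mesh <- structure(list(vertices = v), class = "TriangleMesh")
  expect_equal(attribute_vertices(mesh, m), c(1L, 1L))
  # ligand-only mesh attributes only ligand atoms
  tc <- make_toy_complex(15, 2.0, seed = 4)
  lig <- select_subunit(tc$model, list(chains = "A",
                                       residues = list(A = c(900, 900))))
  mesh_l <- compute_ses_mesh(lig, surface_params())
  expect_true(all(lig$atoms$is_ligand[mesh_l$vertex_atom]))
})

test_that("exact nearest-vertex distances match brute force", {
  set.seed(42)
  ref <- matrix(runif(3 * 200, -10, 10), ncol = 3)
  query <- matrix(runif(3 * 50, -12, 12), ncol = 3)
  got <- glueprint:::cpp_nearest_point_dist(query, ref)
  expect_equal(got, brute_nn_dist(query, ref), tolerance = 1e-12)
})

test_that("mesh export writes valid OBJ and PLY", {
  mesh <- compute_ses_mesh(one_atom_model(1.7), surface_params())
  fo <- tempfile(fileext = ".obj")
  write_mesh(mesh, fo, "obj")
  obj <- readLines(fo)
  expect_equal(sum(grepl("^v ", obj)), nrow(mesh$vertices))
  expect_equal(sum(grepl("^f ", obj)), nrow(mesh$triangles))
  fp <- tempfile(fileext = ".ply")
  write_mesh(mesh, fp, "ply", vertex_scalar = mesh$vertex_area)
  ply <- readLines(fp)
  expect_equal(ply[1], "ply")
  expect_true(any(grepl("property float quality", ply)))
})
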