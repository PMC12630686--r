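#' Surface computation parameters
#'
#' @param probe_radius solvent probe radius in Angstrom (1.4 = water).
#' @param grid_spacing SES grid spacing in Angstrom, in (0.1, 1].
#' @param sasa_points quadrature points per atom for the deterministic
#'   generalized-spiral Shrake-Rupley SASA.
#' @export
surface_params <- function(probe_radius = 1.4, grid_spacing = 0.5,
                           sasa_points = 960) {
  if (probe_radius <= 0) stop("probe_radius must be > 0")
  if (grid_spacing <= 0.1 || grid_spacing > 1.0)
    stop("grid_spacing must lie in (0.1, 1.0] Angstrom")
  if (sasa_points < 16) stop("sasa_points too small")
  structure(list(probe_radius = probe_radius, grid_spacing = grid_spacing,
                 sasa_points = as.integer(sasa_points)),
            class = "SurfaceParams")
}

require_radii <- function(model) {
  if (anyNA(model$atoms$radius))
    stop("radii unassigned: call assign_radii() first")
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Deterministic spiral-point quadrature: per atom,
#' area = (exposed points / total points) * 4 pi (r + probe)^2. An isolated
#' atom is exact by construction (every point exposed).
#'
#' @param model `StructureModel` with radii assigned.
#' @param params [surface_params()].
#' @return object of class `SasaResult` with `per_atom_area`, `total`,
#'   `probe_radius`, `n_sample_points`.
#' @export
compute_sasa <- function(model, params = surface_params()) {
  stopifnot(inherits(model, "StructureModel"))
  require_radii(model)
  res <- cpp_sasa(coords(model), model$atoms$radius, params$probe_radius,
                  params$sasa_points, FALSE)
  per_atom <- as.numeric(res$per_atom_area)
  structure(list(per_atom_area = per_atom, total = sum(per_atom),
                 probe_radius = params$probe_radius,
                 n_sample_points = params$sasa_points),
            class = "SasaResult")
}

#' Solvent-excluded (molecular) surface mesh
#'
#' Probe-rolling construction on a regular grid: the signed field is the
#' minimum of (a) the negated signed distance to the union of probe-expanded
#' spheres and (b) `dist(x, exposed SAS samples) - probe`; its zero level set
#' is the SES, triangulated by marching tetrahedra (closed, orientable).
#' Vertices carry one-third-of-incident-triangle areas ([vertex_areas()]) and
#' a nearest-atom attribution ([attribute_vertices()]).
#'
#' @param model `StructureModel` with radii assigned.
#' @param params [surface_params()]; `grid_spacing` must not exceed the
#'   smallest atomic radius.
#' @param attribute compute per-vertex nearest-atom attribution (default TRUE).
#' @return object of class `TriangleMesh`: `vertices` (n x 3), `triangles`
#'   (m x 3, 1-based), `vertex_area`, `vertex_atom`, `probe_radius`,
#'   `grid_spacing`.
#' @export
compute_ses_mesh <- function(model, params = surface_params(),
                             attribute = TRUE) {
  stopifnot(inherits(model, "StructureModel"))
  require_radii(model)
  r <- model$atoms$radius
  if (params$grid_spacing > min(r))
    stop("grid_spacing (", params$grid_spacing,
         ") exceeds the smallest atomic radius (", min(r),
         "): grid too coarse")
  xyz <- coords(model)
  sas <- cpp_sasa(xyz, r, params$probe_radius, params$sasa_points, TRUE)
  raw <- cpp_ses_mesh(xyz, r, params$probe_radius, params$grid_spacing,
                      sas$points)
  mesh <- structure(
    list(vertices = raw$vertices, triangles = raw$triangles,
         vertex_area = NULL, vertex_atom = NULL,
         probe_radius = params$probe_radius,
         grid_spacing = params$grid_spacing),
    class = "TriangleMesh")
  mesh$vertex_area <- vertex_areas(mesh)
  if (attribute) mesh$vertex_atom <- attribute_vertices(mesh, model)
  mesh
}

#' @export
print.TriangleMesh <- function(x, ...) {
  cat(sprintf(
    "<TriangleMesh: %d vertices, %d triangles, area %.2f A^2, grid %.2f A>\n",
    nrow(x$vertices), nrow(x$triangles), mesh_area(x), x$grid_spacing))
  invisible(x)
}

triangle_areas <- function(mesh) {
  v <- mesh$vertices
  t1 <- mesh$triangles[, 1]; t2 <- mesh$triangles[, 2]
  t3 <- mesh$triangles[, 3]
  u <- v[t2, , drop = FALSE] - v[t1, , drop = FALSE]
  w <- v[t3, , drop = FALSE] - v[t1, , drop = FALSE]
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Total mesh area
#' @param mesh a `TriangleMesh`.
#' @export
mesh_area <- function(mesh) sum(triangle_areas(mesh))

#' Per-vertex areas of a triangle mesh
#'
#' Each vertex receives one third of the summed areas of its incident
#' triangles, so vertex areas conserve the total mesh area exactly.
#' Degenerate zero-area triangles contribute 0.
#'
#' @param mesh a `TriangleMesh`.
#' @return numeric vector, one area per vertex (Angstrom^2).
#' @export
vertex_areas <- function(mesh) {
  ta <- triangle_areas(mesh)
  nv <- nrow(mesh$vertices)
  va <- numeric(nv)
  third <- ta / 3
  for (c in 1:3) {
    acc <- rowsum(third, group = mesh$triangles[, c])
    idx <- as.integer(rownames(acc))
    va[idx] <- va[idx] + acc[, 1]
  }
  va
}

#' Attribute mesh vertices to atoms
#'
#' Each vertex is assigned the atom minimizing the surface distance
#' `|vertex - center| - radius` (not the centre distance, so attribution is
#' correct when radii differ); ties break to the lowest atom index.
#'
#' @param mesh a `TriangleMesh` in the same frame as `model`.
#' @param model `StructureModel` with radii assigned.
#' @return integer vector of atom row indices, one per vertex.
#' @export
attribute_vertices <- function(mesh, model) {
  require_radii(model)
  as.integer(cpp_nearest_atom(mesh$vertices, coords(model),
                              model$atoms$radius))
}

#' Export a mesh to Wavefront OBJ or PLY
#'
#' @param mesh a `TriangleMesh`.
#' @param path output path.
#' @param format `"obj"` or `"ply"`.
#' @param vertex_scalar optional per-vertex scalar written as a comment block
#'   (OBJ) or `quality` property (PLY), e.g. interface labels.
#' @export
write_mesh <- function(mesh, path, format = c("obj", "ply"),
                       vertex_scalar = NULL) {
  format <- match.arg(format)
  v <- mesh$vertices; tr <- mesh$triangles
  if (format == "obj") {
    lines <- c(sprintf("v %.4f %.4f %.4f", v[, 1], v[, 2], v[, 3]),
               sprintf("f %d %d %d", tr[, 1], tr[, 2], tr[, 3]))
    if (!is.null(vertex_scalar))
      lines <- c(sprintf("# vs %d %.6f", seq_len(nrow(v)), vertex_scalar),
                 lines)
  } else {
    hdr <- c("ply", "format ascii 1.0",
             sprintf("element vertex %d", nrow(v)),
             "property float x", "property float y", "property float z",
             if (!is.null(vertex_scalar)) "property float quality",
             sprintf("element face %d", nrow(tr)),
             "property list uchar int vertex_indices", "end_header")
    vl <- if (is.null(vertex_scalar))
      sprintf("%.4f %.4f %.4f", v[, 1], v[, 2], v[, 3])
    else sprintf("%.4f %.4f %.4f %.6f", v[, 1], v[, 2], v[, 3], vertex_scalar)
    lines <- c(hdr, vl,
               sprintf("3 %d %d %d", tr[, 1] - 1, tr[, 2] - 1, tr[, 3] - 1))
  }
  writeLines(lines, path)
  invisible(path)
}
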