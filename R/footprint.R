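#' Buried solvent-accessible surface area of a partitioned complex
#'
#' For each subunit S of the partition,
#' `buried(S) = SASA(S alone) - SASA(S within the complex)`, where the
#' in-complex term counts only S's atoms but lets every other atom of the
#' complex occlude them. The total is the sum over subunits.
#'
#' @param complex `StructureModel` of the full complex, radii assigned.
#' @param partition a [partition_spec()] with disjoint subunits.
#' @param params [surface_params()].
#' @return list with `per_subunit` (named numeric, Angstrom^2) and `total`.
#' @export
buried_sasa <- function(complex, partition, params = surface_params()) {
  stopifnot(inherits(complex, "StructureModel"))
  require_radii(complex)
  masks <- check_partition(complex, partition)
  in_complex <- compute_sasa(complex, params)$per_atom_area
  per <- vapply(names(partition$subunits), function(nm) {
    mask <- masks[[nm]]
    if (!any(mask)) stop("subunit '", nm, "' selects no atoms")
    sub <- structure_model(complex$atoms[mask, , drop = FALSE],
                           ligand_codes = complex$ligand_codes,
                           label = nm)
    alone <- compute_sasa(sub, params)$total
    alone - sum(in_complex[mask])
  }, numeric(1))
  list(per_subunit = per, total = sum(per))
}

#' Label interface vertices of a subunit mesh
#'
#' A subunit-mesh vertex is an interface vertex when its exact
#' nearest-vertex distance to the complex mesh exceeds `threshold`:
#' surface that is present on the isolated subunit but has no counterpart on
#' the complex surface is surface buried by complex formation. Both meshes
#' must be in the same coordinate frame (the subunit extracted from the
#' complex without re-orientation) and built with the same grid parameters.
#'
#' @param subunit_mesh,complex_mesh `TriangleMesh` objects.
#' @param threshold distance threshold in Angstrom (default 2.0).
#' @return logical vector, one label per subunit vertex.
#' @export
label_interface_vertices <- function(subunit_mesh, complex_mesh,
                                     threshold = 2.0) {
  stopifnot(inherits(subunit_mesh, "TriangleMesh"),
            inherits(complex_mesh, "TriangleMesh"))
  if (nrow(complex_mesh$vertices) == 0) stop("empty complex mesh")
  d <- cpp_nearest_point_dist(subunit_mesh$vertices, complex_mesh$vertices)
  d > threshold
}

#' Footprint area from interface labels
#'
#' @param subunit_mesh the labelled subunit's mesh.
#' @param labels logical labels from [label_interface_vertices()].
#' @return summed vertex area over labelled vertices (Angstrom^2).
#' @export
footprint_area <- function(subunit_mesh, labels) {
  stopifnot(length(labels) == nrow(subunit_mesh$vertices))
  sum(subunit_mesh$vertex_area[labels])
}

#' Decompose a footprint into ligand and protein contributions
#'
#' Labelled vertex areas are summed by the ligand flag of the vertex's
#' attributed atom; ligand + protein equals the footprint area exactly.
#'
#' @param subunit_mesh mesh with `vertex_atom` attribution.
#' @param labels logical interface labels.
#' @param model the subunit `StructureModel` the mesh was built from.
#' @return list with `ligand_area` and `protein_area` (Angstrom^2).
#' @export
decompose_footprint <- function(subunit_mesh, labels, model) {
  if (is.null(subunit_mesh$vertex_atom))
    stop("mesh lacks vertex-atom attribution: rebuild with attribute = TRUE")
  is_lig <- model$atoms$is_ligand[subunit_mesh$vertex_atom]
  list(ligand_area = sum(subunit_mesh$vertex_area[labels & is_lig]),
       protein_area = sum(subunit_mesh$vertex_area[labels & !is_lig]))
}

#' Classify an interface by its total buried SASA
#'
#' Bands follow the sizes commonly quoted for protein-protein interfaces:
#' transient interactions bury roughly 800-1200 A^2 while obligate homodimers
#' bury more.
#'
#' @param total_buried_sasa total buried SASA in Angstrom^2 (>= 0).
#' @param transient_band numeric length-2: the transient range.
#' @return one of `"below-transient"`, `"transient"`, `"obligate-range"`.
#' @export
classify_interface <- function(total_buried_sasa,
                               transient_band = c(800, 1200)) {
  if (!is.finite(total_buried_sasa) || total_buried_sasa < 0)
    stop("buried SASA must be a non-negative number")
  if (total_buried_sasa < transient_band[1]) "below-transient"
  else if (total_buried_sasa <= transient_band[2]) "transient"
  else "obligate-range"
}

#' Full interface footprint analysis of a partitioned complex
#'
#' Builds the complex SES mesh and one mesh per subunit (identical grid
#' parameters), labels interface vertices with the distance rule, computes
#' footprint areas with ligand/protein decomposition, and buried SASA.
#'
#' @param complex `StructureModel`, radii assigned.
#' @param partition [partition_spec()].
#' @param params [surface_params()].
#' @param threshold interface labelling threshold in Angstrom.
#' @return object of class `InterfaceSummary`: `per_subunit` (list of
#'   `FootprintResult`), `total_buried_sasa`, `classification`, `threshold`.
#' @export
interface_footprints <- function(complex, partition,
                                 params = surface_params(), threshold = 2.0) {
  masks <- check_partition(complex, partition)
  bs <- buried_sasa(complex, partition, params)
  complex_mesh <- compute_ses_mesh(complex, params, attribute = FALSE)
  per <- lapply(names(partition$subunits), function(nm) {
    mask <- masks[[nm]]
    sub <- structure_model(complex$atoms[mask, , drop = FALSE],
                           ligand_codes = complex$ligand_codes, label = nm)
    mesh <- compute_ses_mesh(sub, params, attribute = TRUE)
    labels <- label_interface_vertices(mesh, complex_mesh, threshold)
    dec <- decompose_footprint(mesh, labels, sub)
    structure(list(subunit_name = nm,
                   interface_vertices = which(labels),
                   footprint_area = footprint_area(mesh, labels),
                   ligand_area = dec$ligand_area,
                   protein_area = dec$protein_area,
                   buried_sasa_subunit = unname(bs$per_subunit[nm]),
                   threshold = threshold,
                   mesh = mesh, labels = labels),
              class = "FootprintResult")
  })
  names(per) <- names(partition$subunits)
  structure(list(per_subunit = per,
                 total_buried_sasa = bs$total,
                 classification = classify_interface(max(0, bs$total)),
                 threshold = threshold,
                 params = params,
                 complex_mesh = complex_mesh),
            class = "InterfaceSummary")
}

#' @export
print.InterfaceSummary <- function(x, ...) {
  cat(sprintf("<InterfaceSummary: buried SASA %.1f A^2 (%s), threshold %.1f A>\n",
              x$total_buried_sasa, x$classification, x$threshold))
  for (fp in x$per_subunit)
    cat(sprintf("  %s: footprint %.1f A^2 (ligand %.1f, protein %.1f)\n",
                fp$subunit_name, fp$footprint_area, fp$ligand_area,
                fp$protein_area))
  invisible(x)
}
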