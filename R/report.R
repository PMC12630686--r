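#' Configuration for a full complex analysis
#'
#' Collects every tunable of the pipeline so a report can be reproduced from
#' its parameter echo alone.
#'
#' @param input path to a PDB/mmCIF file, or an in-memory `StructureModel`.
#' @param format `"auto"`, `"pdb"` or `"mmcif"` (ignored for in-memory input).
#' @param partition a [partition_spec()]; when NULL, one subunit per chain.
#' @param ligand_codes residue codes flagged as ligand.
#' @param params [surface_params()].
#' @param threshold interface labelling threshold in Angstrom (default 2.0).
#' @param threshold_scan thresholds for the always-included sensitivity block.
#' @param criteria [contact_criteria()].
#' @param cis_chains chains of the reference (cis) protomer for contact
#'   labelling.
#' @param contacts,rh,ligand_geometry stage toggles.
#' @param ring_atoms optional list of two atom-name vectors defining the two
#'   ring planes of the ligand (for the spiro dihedral); NULL skips it.
#' @param radius_overrides named per-element radius overrides.
#' @param label report label.
#' @export
analysis_config <- function(input, format = "auto", partition = NULL,
                            ligand_codes = character(),
                            params = surface_params(), threshold = 2.0,
                            threshold_scan = c(1.5, 2.0, 2.5),
                            criteria = contact_criteria(),
                            cis_chains = NULL, contacts = TRUE, rh = TRUE,
                            ligand_geometry = TRUE, ring_atoms = NULL,
                            radius_overrides = NULL, label = NULL) {
  if (threshold <= 0) stop("threshold must be > 0")
  structure(list(input = input, format = format, partition = partition,
                 ligand_codes = ligand_codes, params = params,
                 threshold = threshold, threshold_scan = threshold_scan,
                 criteria = criteria, cis_chains = cis_chains,
                 contacts = contacts, rh = rh,
                 ligand_geometry = ligand_geometry, ring_atoms = ring_atoms,
                 radius_overrides = radius_overrides,
                 label = label), class = "AnalysisConfig")
}

config_echo <- function(config, model) {
  list(label = config$label %||% model$label,
       format = config$format,
       ligand_codes = config$ligand_codes,
       probe_radius_A = config$params$probe_radius,
       grid_spacing_A = config$params$grid_spacing,
       sasa_points = config$params$sasa_points,
       threshold_A = config$threshold,
       threshold_scan_A = config$threshold_scan,
       contact_bands_A = unclass(config$criteria),
       cis_chains = config$cis_chains,
       subunits = lapply(config$partition$subunits, function(s)
         if (is.character(s)) list(chains = s) else s),
       tool_version = as.character(utils::packageVersion("glueprint")))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Analyse a complex end to end
#'
#' Runs load -> radii -> partition -> SASA -> SES meshes (complex and each
#' subunit) -> interface labelling -> footprints with ligand/protein
#' decomposition -> ligand-pair geometry -> polar contacts -> hydrodynamic
#' radius, and returns a structured report. A threshold-sensitivity block
#' (footprints at `threshold_scan`) is always included, since the labelling
#' threshold is the one fixed point of the footprint definition.
#'
#' @param config an [analysis_config()].
#' @return object of class `AnalysisReport` (a nested list; see
#'   [write_report()] for serialization).
#' @export
analyze_complex <- function(config) {
  stopifnot(inherits(config, "AnalysisConfig"))
  model <- stage("load", {
    if (inherits(config$input, "StructureModel")) config$input
    else load_structure(config$input, config$format,
                        ligand_codes = config$ligand_codes)
  })
  model <- stage("radii", {
    if (anyNA(model$atoms$radius))
      assign_radii(model, radius_table(overrides = config$radius_overrides))
    else model
  })
  partition <- config$partition %||%
    partition_spec(setNames(lapply(model$chains, function(ch)
      list(chains = ch)), model$chains))
  config$partition <- partition

  summary <- stage("footprints",
                   interface_footprints(model, partition, config$params,
                                        config$threshold))
  scan <- stage("threshold_scan", {
    lapply(setNames(config$threshold_scan,
                    sprintf("threshold_%.1f", config$threshold_scan)),
           function(th) {
             vapply(summary$per_subunit, function(fp) {
               labels <- label_interface_vertices(fp$mesh,
                                                  summary$complex_mesh, th)
               footprint_area(fp$mesh, labels)
             }, numeric(1))
           })
  })

  lig <- NULL
  n_lig_copies <- length(unique(with(model$atoms[model$atoms$is_ligand, ],
                                     paste(chain, resseq))))
  if (config$ligand_geometry && n_lig_copies == 2)
    lig <- stage("ligand_geometry", ligand_pair_rmsd(model))

  planes <- NULL
  if (!is.null(config$ring_atoms) && n_lig_copies >= 1)
    planes <- stage("ring_planes", {
      a <- model$atoms
      lig_atoms <- a[a$is_ligand, , drop = FALSE]
      first <- lig_atoms[paste(lig_atoms$chain, lig_atoms$resseq) ==
                           unique(paste(lig_atoms$chain,
                                        lig_atoms$resseq))[1], ,
                         drop = FALSE]
      fits <- lapply(config$ring_atoms, function(nms) {
        sel <- first[match(nms, first$name), , drop = FALSE]
        if (anyNA(sel$x)) stop("ring atoms not found: ",
                               paste(nms[is.na(sel$x)], collapse = ","))
        best_fit_plane(as.matrix(sel[, c("x", "y", "z")]))
      })
      list(fit1 = fits[[1]], fit2 = fits[[2]],
           angle_deg = plane_angle(fits[[1]], fits[[2]]))
    })

  contacts <- NULL
  if (config$contacts && length(partition$subunits) >= 2)
    contacts <- stage("contacts", {
      nms <- names(partition$subunits)
      find_polar_contacts(model, partition$subunits[[nms[1]]],
                          partition$subunits[[nms[2]]],
                          criteria = config$criteria,
                          cis_chains = config$cis_chains)
    })

  rh <- NULL
  if (config$rh) rh <- stage("rh", predict_rh(model))

  structure(list(
    parameters = config_echo(config, model),
    n_atoms = n_atoms(model),
    interface = list(
      total_buried_sasa_A2 = summary$total_buried_sasa,
      classification = summary$classification,
      per_subunit = lapply(summary$per_subunit, function(fp) list(
        subunit = fp$subunit_name,
        footprint_area_A2 = fp$footprint_area,
        ligand_area_A2 = fp$ligand_area,
        protein_area_A2 = fp$protein_area,
        buried_sasa_A2 = fp$buried_sasa_subunit,
        n_interface_vertices = length(fp$interface_vertices)))),
    threshold_sensitivity_A2 = scan,
    ligand_rmsd_A = if (!is.null(lig)) lig$rmsd,
    ligand_n_atoms = if (!is.null(lig)) lig$n_atoms,
    ring_plane_angle_deg = if (!is.null(planes)) planes$angle_deg,
    contacts = contacts,
    contact_counts = if (!is.null(contacts))
      as.list(table(factor(contacts$kind,
                           levels = c("canonical_hbond", "weak_hbond",
                                      "ch_o_contact")))),
    rh_nm = if (!is.null(rh)) rh$rh,
    rh_method = if (!is.null(rh)) rh$method,
    summary_detail = summary),
    class = "AnalysisReport")
}

#' @export
print.AnalysisReport <- function(x, ...) {
  cat(sprintf("<AnalysisReport '%s': %d atoms>\n", x$parameters$label,
              x$n_atoms))
  cat(sprintf("  buried SASA %.1f A^2 (%s)\n",
              x$interface$total_buried_sasa_A2, x$interface$classification))
  for (fp in x$interface$per_subunit)
    cat(sprintf("  %s: footprint %.1f A^2 (ligand %.1f / protein %.1f)\n",
                fp$subunit, fp$footprint_area_A2, fp$ligand_area_A2,
                fp$protein_area_A2))
  if (!is.null(x$ligand_rmsd_A))
    cat(sprintf("  ligand-pair RMSD %.3f A (%d atoms)\n", x$ligand_rmsd_A,
                x$ligand_n_atoms))
  if (!is.null(x$ring_plane_angle_deg))
    cat(sprintf("  ring-plane dihedral %.1f deg\n", x$ring_plane_angle_deg))
  if (!is.null(x$contact_counts))
    cat(sprintf("  contacts: %d canonical, %d weak, %d C-H...O\n",
                x$contact_counts$canonical_hbond, x$contact_counts$weak_hbond,
                x$contact_counts$ch_o_contact))
  if (!is.null(x$rh_nm))
    cat(sprintf("  predicted Rh %.2f nm (%s)\n", x$rh_nm, x$rh_method))
  invisible(x)
}

#' Serialize an analysis report
#'
#' Writes `report.json` (canonical, without the bulky mesh detail), a
#' per-subunit `footprints.csv`, and `contacts.csv` when contacts were
#' computed. A timestamp is the only non-reproducible field.
#'
#' @param report an `AnalysisReport`.
#' @param dir output directory (created if needed).
#' @param timestamp include a timestamp field (default TRUE).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, timestamp = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- unclass(report)
  out$summary_detail <- NULL
  out$contacts <- NULL
  if (timestamp) out$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(out, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  fp <- do.call(rbind, lapply(report$interface$per_subunit, function(f)
    data.frame(subunit = f$subunit, footprint_area_A2 = f$footprint_area_A2,
               ligand_area_A2 = f$ligand_area_A2,
               protein_area_A2 = f$protein_area_A2,
               buried_sasa_A2 = f$buried_sasa_A2)))
  fp$total_buried_sasa_A2 <- report$interface$total_buried_sasa_A2
  fp$classification <- report$interface$classification
  write.csv(fp, file.path(dir, "footprints.csv"), row.names = FALSE)
  if (!is.null(report$contacts))
    write.csv(as.data.frame(report$contacts),
              file.path(dir, "contacts.csv"), row.names = FALSE)
  invisible(dir)
}

#' Compare footprints across structures
#'
#' Runs [analyze_complex()] per configuration and tabulates one summary row
#' per structure; per-structure failures are reported in the row (column
#' `error`) and the run continues.
#'
#' @param configs list of [analysis_config()] objects.
#' @return data.frame: label, footprint/ligand/protein areas of the first
#'   subunit, total buried SASA, classification, error.
#' @export
compare_footprints <- function(configs) {
  stopifnot(length(configs) >= 1)
  rows <- lapply(configs, function(cfg) {
    res <- tryCatch(analyze_complex(cfg), error = function(e)
      conditionMessage(e))
    if (is.character(res))
      return(data.frame(label = cfg$label %||% "?", footprint_area_A2 = NA,
                        ligand_area_A2 = NA, protein_area_A2 = NA,
                        total_buried_sasa_A2 = NA, classification = NA,
                        error = res))
    f1 <- res$interface$per_subunit[[1]]
    data.frame(label = res$parameters$label,
               footprint_area_A2 = f1$footprint_area_A2,
               ligand_area_A2 = f1$ligand_area_A2,
               protein_area_A2 = f1$protein_area_A2,
               total_buried_sasa_A2 = res$interface$total_buried_sasa_A2,
               classification = res$interface$classification,
               error = NA_character_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
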