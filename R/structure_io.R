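#' @useDynLib glueprint, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames
#' @importFrom utils head write.csv
NULL

WATER_CODES <- c("HOH", "WAT", "H2O", "DOD", "TIP", "TIP3", "SOL")

ATOM_COLS <- c("serial", "name", "element", "resname", "resseq", "chain",
               "altloc", "occupancy", "x", "y", "z", "radius",
               "is_ligand", "is_hydrogen")

#' Construct a structure model
#'
#' A `StructureModel` is an ordered atom table plus chain and ligand metadata;
#' it is the universal input to every geometry operation in the package.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resseq`, `chain`, `altloc`, `occupancy`, `x`, `y`, `z`,
#'   `radius` (NA until [assign_radii()] is called), `is_ligand`,
#'   `is_hydrogen`.
#' @param ligand_codes character vector of residue codes treated as ligand.
#' @param label free-text label carried through reports.
#' @return an object of class `StructureModel`.
#' @export
structure_model <- function(atoms, ligand_codes = character(), label = "") {
  stopifnot(is.data.frame(atoms))
  missing_cols <- setdiff(ATOM_COLS, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  atoms <- atoms[, ATOM_COLS]
  rownames(atoms) <- NULL
  if (nrow(atoms) > 0 && !all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  structure(
    list(atoms = atoms,
         chains = unique(atoms$chain),
         ligand_codes = unique(as.character(ligand_codes)),
         label = label),
    class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  cat(sprintf("<StructureModel '%s': %d atoms, chains [%s], %d ligand atoms>\n",
              x$label, nrow(x$atoms), paste(x$chains, collapse = ","),
              sum(x$atoms$is_ligand)))
  invisible(x)
}

#' Number of atoms in a model
#' @param model a `StructureModel`.
#' @export
n_atoms <- function(model) nrow(model$atoms)

#' Coordinate matrix of a model
#' @param model a `StructureModel`.
#' @return numeric n x 3 matrix in Angstrom.
#' @export
coords <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z"), drop = FALSE])
}

element_from_name <- function(name, resname) {
  # PDB convention: element often derivable from the atom-name stem
  nm <- toupper(trimws(name))
  stem <- sub("^[0-9']+", "", nm)
  two <- substr(stem, 1, 2)
  ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "CA") &
           nchar(nm) > 1 & !grepl("^CA$|^CB$|^CG", nm),
         two, substr(stem, 1, 1))
}

filter_atoms <- function(atoms, keep_waters, keep_hydrogens) {
  if (!keep_waters) atoms <- atoms[!(atoms$resname %in% WATER_CODES), ,
                                   drop = FALSE]
  if (!keep_hydrogens) atoms <- atoms[!atoms$is_hydrogen, , drop = FALSE]
  if (nrow(atoms) == 0) return(atoms)
  # highest-occupancy altloc per (chain, resseq, name); tie -> first seen
  key <- paste(atoms$chain, atoms$resseq, atoms$resname, atoms$name, sep = "|")
  ord <- order(factor(key, levels = unique(key)), -atoms$occupancy,
               seq_len(nrow(atoms)))
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resseq, atoms$resname,
                                   atoms$name, sep = "|")), , drop = FALSE]
  atoms
}

parse_pdb <- function(lines, ligand_codes) {
  sel <- grepl("^(ATOM  |HETATM)", lines)
  rec <- lines[sel]
  if (length(rec) == 0) stop("no ATOM/HETATM records found (parse error)")
  pad <- function(s, n) formatC(s, width = n, flag = "-")
  rec <- vapply(rec, pad, "", n = 80, USE.NAMES = FALSE)
  num <- function(s) suppressWarnings(as.numeric(s))
  atoms <- data.frame(
    record  = substr(rec, 1, 6),
    serial  = as.integer(num(substr(rec, 7, 11))),
    name    = trimws(substr(rec, 13, 16)),
    altloc  = trimws(substr(rec, 17, 17)),
    resname = trimws(substr(rec, 18, 20)),
    chain   = trimws(substr(rec, 22, 22)),
    resseq  = as.integer(num(substr(rec, 23, 26))),
    x = num(substr(rec, 31, 38)),
    y = num(substr(rec, 39, 46)),
    z = num(substr(rec, 47, 54)),
    occupancy = num(substr(rec, 55, 60)),
    element   = trimws(substr(rec, 77, 78)),
    stringsAsFactors = FALSE)
  bad <- which(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))
  if (length(bad))
    stop("unparseable coordinate in ATOM/HETATM record ", bad[1])
  atoms$occupancy[!is.finite(atoms$occupancy)] <- 1
  noel <- atoms$element == ""
  atoms$element[noel] <- element_from_name(atoms$name[noel],
                                           atoms$resname[noel])
  atoms$element <- toupper(atoms$element)
  atoms$is_hydrogen <- atoms$element %in% c("H", "D")
  if (length(ligand_codes)) {
    atoms$is_ligand <- atoms$resname %in% ligand_codes
  } else {
    atoms$is_ligand <- atoms$record == "HETATM" &
      !(atoms$resname %in% WATER_CODES)
  }
  atoms$record <- NULL
  atoms
}

cif_tokenize <- function(lines) {
  lines <- lines[!grepl("^\\s*#", lines)]
  toks <- regmatches(lines,
                     gregexpr("'[^']*'|\"[^\"]*\"|\\S+", lines, perl = TRUE))
  toks <- unlist(toks, use.names = FALSE)
  gsub("^['\"]|['\"]$", "", toks)
}

parse_mmcif <- function(lines, ligand_codes) {
  # locate the atom_site loop
  starts <- grep("^\\s*loop_\\s*$", lines)
  block <- NULL
  for (s in starts) {
    i <- s + 1
    fields <- character()
    while (i <= length(lines) && grepl("^\\s*_", lines[i])) {
      fields <- c(fields, trimws(strsplit(trimws(lines[i]), "\\s+")[[1]][1]))
      i <- i + 1
    }
    if (any(grepl("^_atom_site\\.", fields))) {
      j <- i
      while (j <= length(lines) &&
             !grepl("^\\s*(loop_|_[A-Za-z]|#\\s*$|data_)", lines[j]))
        j <- j + 1
      block <- list(fields = fields, body = lines[i:(j - 1)])
      break
    }
  }
  if (is.null(block)) stop("no _atom_site loop found (parse error)")
  fields <- sub("^_atom_site\\.", "", block$fields)
  toks <- cif_tokenize(block$body)
  nf <- length(fields)
  if (length(toks) %% nf != 0)
    stop("malformed _atom_site loop: ", length(toks), " tokens for ",
         nf, " fields")
  m <- matrix(toks, ncol = nf, byrow = TRUE)
  colnames(m) <- fields
  get <- function(a, b = NULL, default = NA_character_) {
    if (a %in% fields) return(m[, a])
    if (!is.null(b) && b %in% fields) return(m[, b])
    rep(default, nrow(m))
  }
  num <- function(s) suppressWarnings(as.numeric(s))
  occ <- num(get("occupancy", default = "1"))
  occ[!is.finite(occ)] <- 1
  atoms <- data.frame(
    record  = get("group_PDB", default = "ATOM"),
    serial  = as.integer(num(get("id", default = NA))),
    name    = get("auth_atom_id", "label_atom_id"),
    altloc  = get("label_alt_id", default = ""),
    resname = get("auth_comp_id", "label_comp_id"),
    chain   = get("auth_asym_id", "label_asym_id"),
    resseq  = as.integer(num(get("auth_seq_id", "label_seq_id"))),
    x = num(get("Cartn_x")), y = num(get("Cartn_y")), z = num(get("Cartn_z")),
    occupancy = occ,
    element = toupper(get("type_symbol", default = "")),
    stringsAsFactors = FALSE)
  atoms$altloc[atoms$altloc %in% c(".", "?")] <- ""
  atoms$name <- gsub('"', "", atoms$name)
  if (anyNA(atoms$serial)) atoms$serial <- seq_len(nrow(atoms))
  bad <- which(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))
  if (length(bad)) stop("unparseable coordinate in atom_site row ", bad[1])
  noel <- atoms$element %in% c("", ".", "?")
  atoms$element[noel] <- element_from_name(atoms$name[noel],
                                           atoms$resname[noel])
  atoms$is_hydrogen <- atoms$element %in% c("H", "D")
  if (length(ligand_codes)) {
    atoms$is_ligand <- atoms$resname %in% ligand_codes
  } else {
    atoms$is_ligand <- atoms$record == "HETATM" &
      !(atoms$resname %in% WATER_CODES)
  }
  atoms$record <- NULL
  atoms
}

#' Load an atomic structure from PDB or mmCIF
#'
#' Waters are removed, hydrogens are dropped (all downstream geometry is
#' heavy-atom based), and for alternate locations only the highest-occupancy
#' conformer is kept (tie: first encountered). Radii are left unassigned
#' (`NA`) until [assign_radii()].
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by extension).
#' @param ligand_codes residue codes flagged as ligand; when empty, HETATM
#'   (non-water) records are used as a fallback heuristic.
#' @param label optional label; defaults to the file name.
#' @return a [structure_model()].
#' @export
load_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           ligand_codes = character(), label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  lines <- readLines(path, warn = FALSE)
  atoms <- if (format == "pdb") parse_pdb(lines, ligand_codes)
           else parse_mmcif(lines, ligand_codes)
  atoms <- filter_atoms(atoms, keep_waters = FALSE, keep_hydrogens = FALSE)
  if (nrow(atoms) == 0)
    stop("empty model: no atoms remain after water/hydrogen filtering")
  atoms$radius <- NA_real_
  structure_model(atoms, ligand_codes = ligand_codes,
                  label = label %||% basename(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bondi-style van der Waals radius table
#'
#' @param overrides named numeric vector of per-element overrides in Angstrom.
#' @param default_radius radius for elements absent from the table.
#' @return object of class `RadiusTable`.
#' @export
radius_table <- function(overrides = NULL, default_radius = 1.70) {
  radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80,
             F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90)
  if (!is.null(overrides)) radii[toupper(names(overrides))] <- overrides
  if (any(radii <= 0.5 | radii >= 3.0) || default_radius <= 0.5 ||
      default_radius >= 3.0)
    stop("radii must lie in (0.5, 3.0) Angstrom")
  structure(list(radii = radii, default_radius = default_radius),
            class = "RadiusTable")
}

#' Assign van der Waals radii by element
#'
#' Idempotent; unknown elements fall back to the table's default radius with
#' one warning per element.
#'
#' @param model a `StructureModel` (non-empty).
#' @param table a [radius_table()].
#' @return the model with `radius` filled in.
#' @export
assign_radii <- function(model, table = radius_table()) {
  stopifnot(inherits(model, "StructureModel"), inherits(table, "RadiusTable"))
  if (n_atoms(model) == 0) stop("empty model")
  el <- toupper(model$atoms$element)
  r <- unname(table$radii[el])
  unknown <- unique(el[is.na(r)])
  for (u in unknown)
    warning("unknown element '", u, "': using default radius ",
            table$default_radius, " Angstrom", call. = FALSE)
  r[is.na(r)] <- table$default_radius
  model$atoms$radius <- r
  model
}

#' Define a subunit partition of a complex
#'
#' Each subunit is a named selection: a set of chain IDs, optionally
#' restricted to residue ranges, optionally restricted in which ligand codes
#' it owns. Subunits must be disjoint.
#'
#' @param subunits named list; each element a list with `chains` (character),
#'   optional `residues` (named list chain -> c(lo, hi)), optional
#'   `ligand_codes` (restrict ligand atoms of this subunit to these codes),
#'   optional `include_ligand` (default TRUE).
#' @param name partition label.
#' @export
partition_spec <- function(subunits, name = "partition") {
  stopifnot(is.list(subunits), length(subunits) >= 1,
            !is.null(names(subunits)), all(nzchar(names(subunits))))
  structure(list(subunits = subunits, name = name), class = "PartitionSpec")
}

subunit_mask <- function(model, spec) {
  a <- model$atoms
  keep <- a$chain %in% spec$chains
  if (!is.null(spec$residues)) {
    for (ch in names(spec$residues)) {
      rng <- spec$residues[[ch]]
      drop <- a$chain == ch & (a$resseq < rng[1] | a$resseq > rng[2])
      keep <- keep & !drop
    }
  }
  if (isFALSE(spec$include_ligand %||% TRUE)) keep <- keep & !a$is_ligand
  if (!is.null(spec$ligand_codes))
    keep <- keep & (!a$is_ligand | a$resname %in% spec$ligand_codes)
  keep
}

#' Select one subunit of a model
#'
#' @param model a `StructureModel`.
#' @param spec one subunit entry of a [partition_spec()] (list with `chains`
#'   etc.), or a character vector of chain IDs.
#' @return a `StructureModel` preserving atom order and ligand flags.
#' @export
select_subunit <- function(model, spec) {
  stopifnot(inherits(model, "StructureModel"))
  if (is.character(spec)) spec <- list(chains = spec)
  absent <- setdiff(spec$chains, model$chains)
  if (length(absent) && !any(spec$chains %in% model$chains))
    stop("empty selection: chain(s) ", paste(absent, collapse = ","),
         " not present in model")
  keep <- subunit_mask(model, spec)
  if (!any(keep)) stop("empty selection: no atoms match the subunit spec")
  structure_model(model$atoms[keep, , drop = FALSE],
                  ligand_codes = model$ligand_codes, label = model$label)
}

check_partition <- function(model, partition) {
  stopifnot(inherits(partition, "PartitionSpec"))
  masks <- lapply(partition$subunits, function(s) {
    if (is.character(s)) s <- list(chains = s)
    subunit_mask(model, s)
  })
  overlap <- Reduce(`+`, masks)
  if (any(overlap > 1)) stop("partition subunits overlap")
  masks
}

fmt_pdb_name <- function(name, element) {
  # column 13-16; 1-letter elements start in column 14 unless 4 chars long
  ifelse(nchar(name) >= 4 | nchar(element) > 1,
         formatC(name, width = -4), paste0(" ", formatC(name, width = -3)))
}

#' Write a structure to PDB or mmCIF
#'
#' `load_structure(write_structure(m))` reproduces `m` on chain, residue,
#' atom name and coordinates (to 1e-3 Angstrom). Ligand atoms are emitted as
#' HETATM records.
#'
#' @param model non-empty `StructureModel`.
#' @param path output path.
#' @param format `"pdb"` or `"mmcif"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, format = c("pdb", "mmcif")) {
  format <- match.arg(format)
  stopifnot(inherits(model, "StructureModel"))
  a <- model$atoms
  if (nrow(a) == 0) stop("refusing to write an empty model")
  if (format == "pdb") {
    rec <- ifelse(a$is_ligand, "HETATM", "ATOM  ")
    lines <- sprintf(
      "%6s%5d %s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rec, a$serial %% 100000L, fmt_pdb_name(a$name, a$element),
      substr(a$altloc, 1, 1), a$resname, a$chain, a$resseq,
      a$x, a$y, a$z, a$occupancy, 0, toupper(a$element))
    lines <- c(lines, "END")
  } else {
    q <- function(s) ifelse(grepl("[' ]", s) | s == "", paste0('"', s, '"'), s)
    lines <- c(
      paste0("data_", gsub("[^A-Za-z0-9]", "_", model$label %||% "model")),
      "loop_",
      paste0("_atom_site.", c("group_PDB", "id", "type_symbol",
                              "label_atom_id", "label_alt_id",
                              "label_comp_id", "auth_asym_id", "auth_seq_id",
                              "Cartn_x", "Cartn_y", "Cartn_z", "occupancy")),
      sprintf("%s %d %s %s %s %s %s %d %.3f %.3f %.3f %.2f",
              ifelse(a$is_ligand, "HETATM", "ATOM"), a$serial,
              q(toupper(a$element)), q(a$name),
              ifelse(a$altloc == "", ".", a$altloc),
              q(a$resname), q(a$chain), a$resseq, a$x, a$y, a$z, a$occupancy),
      "#")
  }
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) stop("cannot write ", path, ": ",
                                          conditionMessage(e)))
  invisible(path)
}
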