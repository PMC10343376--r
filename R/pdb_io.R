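# PDB and parameter-table I/O.  PDB parsing/writing is delegated to bio3d;
# this layer adds strict validation (truncated records, per-model atom
# counts) and the mapping onto the package's atom table.

# residue names stripped by default before analysis (crystallographic
# water and monatomic ions)
#' @keywords internal
.solvent_residues <- c("HOH", "WAT", "TIP3", "TIP", "SOL", "SPC",
                       "NA", "CL", "K", "MG", "CA2", "SOD", "CLA", "POT")

#' @keywords internal
.validate_pdb_lines <- function(lines) {
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) abort("no ATOM/HETATM records found (empty or non-PDB file)")
  short <- which(rec & nchar(lines) < 54)
  if (length(short) > 0) {
    abort(sprintf("malformed ATOM/HETATM record at line %d (truncated)", short[1]))
  }
  invisible(TRUE)
}

#' Read a structure from a PDB file
#'
#' Reads ATOM/HETATM records into a topology.  Residue ids are taken
#' verbatim from the file (author numbering; XIAP-BIR3 constructs run
#' 248-352).  Coordinates only -- force-field parameters are unset until
#' [read_parameters()] is applied.  Crystallographic waters and monatomic
#' ions are stripped by default and the count is reported.
#'
#' @param path Path to a PDB file.
#' @param segment_overrides Named character vector residue name -> segment,
#'   see [as_topology()].
#' @param strip_solvent Remove water/ion records (default `TRUE`).
#' @param provenance Provenance tag to attach; default `"pdb"`.
#' @return A `bir3_topology`.
#' @export
read_structure <- function(path, segment_overrides = NULL,
                           strip_solvent = TRUE, provenance = "pdb") {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  .validate_pdb_lines(lines)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  atoms <- tibble(
    atom_index = as.integer(at$eleno),
    atom_name = trimws(at$elety),
    residue_name = trimws(at$resid),
    residue_id = as.integer(at$resno),
    x = at$x, y = at$y, z = at$z
  )
  if (strip_solvent) {
    drop <- atoms$residue_name %in% .solvent_residues
    if (any(drop)) {
      inform(sprintf("read_structure: stripped %d solvent/ion atoms", sum(drop)))
      atoms <- atoms[!drop, ]
    }
  }
  if (nrow(atoms) == 0) abort("no atoms left after solvent stripping")
  as_topology(atoms, provenance = provenance,
              segment_overrides = segment_overrides)
}

#' Write a topology (or trajectory) to a PDB file
#'
#' Coordinates are written at standard PDB precision (3 decimals).  A
#' trajectory is written as a multi-model PDB (MODEL/ENDMDL blocks).
#'
#' @param x A `bir3_topology` or `bir3_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  if (inherits(x, "bir3_trajectory")) {
    top <- x$topology
    xyz <- do.call(rbind, lapply(x$frames, function(f) as.vector(t(f))))
  } else {
    top <- x
    xyz <- as.vector(t(topology_coords(top)))
  }
  bio3d::write.pdb(pdb = NULL, file = path, xyz = xyz,
                   resno = top$residue_id, resid = top$residue_name,
                   eleno = top$atom_index, elety = top$atom_name,
                   chain = ifelse(top$segment == "receptor", "A", "B"))
  invisible(path)
}

#' @keywords internal
.count_model_atoms <- function(lines) {
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0) return(NULL)
  ends <- grep("^ENDMDL", lines)
  if (length(ends) != length(model_starts)) abort("unbalanced MODEL/ENDMDL records")
  vapply(seq_along(model_starts), function(i) {
    blk <- lines[model_starts[i]:ends[i]]
    sum(grepl("^(ATOM  |HETATM)", blk))
  }, integer(1))
}

#' Read a conformational ensemble from a multi-model PDB
#'
#' Each MODEL block becomes one frame; frames are ordered by MODEL number.
#' The frame spacing and temperature come from a sidecar config (YAML with
#' fields `frame_interval` and `temperature`) or from the arguments.
#'
#' @param path Multi-model PDB file.
#' @param top The `bir3_topology` the frames belong to (atom counts must
#'   match in every model).
#' @param config Optional path to a YAML sidecar or a list; fields
#'   `frame_interval` (ps), `temperature` (K).  If `NULL` and
#'   `<path>.yaml` exists it is used.
#' @param frame_interval,temperature Fallback values when no config given.
#' @return A `bir3_trajectory`.
#' @export
read_trajectory <- function(path, top, config = NULL,
                            frame_interval = 20, temperature = 303.15) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  .validate_pdb_lines(lines)
  counts <- .count_model_atoms(lines)
  n <- nrow(top)
  if (!is.null(counts)) {
    bad <- which(counts != n)
    if (length(bad) > 0) {
      abort(sprintf("MODEL %d has %d atoms; topology has %d",
                    bad[1], counts[bad[1]], n))
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(counts)) {                       # single-model file
    xyz <- matrix(as.numeric(xyz), nrow = 1)
  }
  if (ncol(xyz) != 3 * n) {
    abort(sprintf("trajectory has %d coordinates per frame; topology needs %d",
                  ncol(xyz), 3 * n))
  }
  frames <- lapply(seq_len(nrow(xyz)), function(i) {
    matrix(xyz[i, ], ncol = 3, byrow = TRUE,
           dimnames = list(NULL, c("x", "y", "z")))
  })
  if (is.null(config) && file.exists(paste0(path, ".yaml"))) {
    config <- paste0(path, ".yaml")
  }
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.list(config)) {
    frame_interval <- config$frame_interval %||% frame_interval
    temperature <- config$temperature %||% temperature
  }
  new_trajectory(top, frames, frame_interval = frame_interval,
                 temperature = temperature)
}

#' Read a per-atom parameter table into a topology
#'
#' The parameter file is a flat comma- or tab-separated table with a header
#' and one row per atom: `atom_index, charge, lj_epsilon, lj_rmin_half,
#' pb_radius, mass` plus optional `group_id` and `hbond_role` columns.
#' Every atom of the topology must appear.  Net receptor and ligand charges
#' are reported.
#'
#' @param top A `bir3_topology`.
#' @param path Parameter table path.
#' @return The parameterized topology.
#' @export
read_parameters <- function(top, path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tab <- suppressMessages(readr::read_delim(
    path, delim = if (grepl("\t", readLines(path, n = 1))) "\t" else ",",
    show_col_types = FALSE))
  need <- c("atom_index", "charge", "lj_epsilon", "lj_rmin_half",
            "pb_radius", "mass")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    abort(paste0("parameter file missing columns: ", paste(miss, collapse = ", ")))
  }
  missing_atoms <- setdiff(top$atom_index, tab$atom_index)
  if (length(missing_atoms) > 0) {
    abort(paste0("parameter file missing atoms with atom_index: ",
                 paste(missing_atoms, collapse = ", ")))
  }
  num <- as.matrix(tab[, setdiff(need, "atom_index")])
  if (any(!is.finite(num))) abort("non-finite value in parameter file")
  m <- match(top$atom_index, tab$atom_index)
  for (col in setdiff(need, "atom_index")) top[[col]] <- tab[[col]][m]
  if ("group_id" %in% names(tab)) top$group_id <- as.character(tab$group_id)[m]
  if ("hbond_role" %in% names(tab)) top$hbond_role <- as.character(tab$hbond_role)[m]
  if (any(top$pb_radius[!top$is_hydrogen] <= 0)) {
    abort("pb_radius must be > 0 for non-hydrogen atoms")
  }
  inform(sprintf(
    "read_parameters: net charge receptor %+.3f e, ligand %+.3f e",
    sum(top$charge[top$segment == "receptor"]),
    sum(top$charge[top$segment == "ligand"])))
  top
}

#' Write a topology's per-atom parameters to a table
#' @param top A parameterized `bir3_topology`.
#' @param path Output path (CSV).
#' @return `path`, invisibly.
#' @export
write_parameters <- function(top, path) {
  readr::write_csv(tibble(
    atom_index = top$atom_index, charge = top$charge,
    lj_epsilon = top$lj_epsilon, lj_rmin_half = top$lj_rmin_half,
    pb_radius = top$pb_radius, mass = top$mass,
    group_id = top$group_id, hbond_role = top$hbond_role
  ), path)
  invisible(path)
}
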