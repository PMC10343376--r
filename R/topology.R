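# Atom tables ("topologies") are tibbles with one row per atom and a
# `bir3_topology` class.  Residue numbering is always kept verbatim from the
# input (XIAP-BIR3 constructs use author numbering 248-352); no renumbering
# ever happens internally.

#' @keywords internal
.topology_cols <- c(
  "atom_index", "atom_name", "residue_name", "residue_id", "segment",
  "group_id", "x", "y", "z", "charge", "lj_epsilon", "lj_rmin_half",
  "pb_radius", "mass", "is_hydrogen", "hbond_role", "ring_id"
)

# Residue names treated as receptor (protein) by default.  Includes the
# CHARMM histidine tautomers and the anionic cysteine used for
# zinc-coordinating residues; everything else is assigned to the ligand.
#' @keywords internal
.receptor_residues <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "HSD", "HSE", "HSP", "CYM"
)

#' Backbone atom names
#' @keywords internal
.backbone_names <- c("N", "CA", "C", "O")

#' Construct a complex topology
#'
#' Builds the atom table used by every downstream analysis.  Parameter
#' columns (charge, Lennard-Jones, PB radius, mass) may be `NA` on
#' construction and filled later with [read_parameters()].
#'
#' @param atoms A data frame with at least `atom_index`, `atom_name`,
#'   `residue_name`, `residue_id`, `x`, `y`, `z`.  Missing optional columns
#'   are added as `NA`/defaults.
#' @param provenance Free-text tag recording where the structure came from
#'   (e.g. `"synthetic"`, `"HMR"`, `"WYF"`).
#' @param segment_overrides Optional named character vector mapping residue
#'   names to `"receptor"` or `"ligand"`, overriding the default assignment
#'   (standard amino-acid names plus HSD/HSE/HSP/CYM go to the receptor,
#'   everything else to the ligand).
#' @return A tibble of class `bir3_topology`, one row per atom.
#' @export
as_topology <- function(atoms, provenance = "unknown", segment_overrides = NULL) {
  atoms <- as_tibble(atoms)
  need <- c("atom_index", "atom_name", "residue_name", "residue_id", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0) {
    abort(paste0("topology is missing columns: ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(atoms$atom_index) > 0) {
    abort("atom_index values must be unique within a topology")
  }
  if (!"segment" %in% names(atoms)) {
    atoms$segment <- ifelse(atoms$residue_name %in% .receptor_residues,
                            "receptor", "ligand")
  }
  if (!is.null(segment_overrides)) {
    hit <- atoms$residue_name %in% names(segment_overrides)
    atoms$segment[hit] <- unname(segment_overrides[atoms$residue_name[hit]])
  }
  if (!all(atoms$segment %in% c("receptor", "ligand"))) {
    abort("segment must be 'receptor' or 'ligand'")
  }
  for (col in c("charge", "lj_epsilon", "lj_rmin_half", "pb_radius", "mass")) {
    if (!col %in% names(atoms)) atoms[[col]] <- NA_real_
  }
  if (!"group_id" %in% names(atoms)) atoms$group_id <- NA_character_
  if (!"is_hydrogen" %in% names(atoms)) {
    atoms$is_hydrogen <- grepl("^[0-9]*H", atoms$atom_name)
  }
  if (!"hbond_role" %in% names(atoms)) atoms$hbond_role <- "none"
  if (!"ring_id" %in% names(atoms)) atoms$ring_id <- NA_integer_
  ok_role <- atoms$hbond_role %in% c("donor_heavy", "acceptor", "polar_h", "none")
  if (!all(ok_role)) abort("hbond_role must be donor_heavy/acceptor/polar_h/none")
  xyz <- c(atoms$x, atoms$y, atoms$z)
  if (any(!is.finite(xyz))) abort("non-finite coordinates in topology")
  atoms <- atoms[, c(.topology_cols)]
  structure(atoms,
            class = c("bir3_topology", class(tibble())),
            provenance = provenance)
}

#' @export
print.bir3_topology <- function(x, ...) {
  cat(sprintf("<bir3_topology> %d atoms (%d receptor, %d ligand), provenance: %s\n",
              nrow(x), sum(x$segment == "receptor"), sum(x$segment == "ligand"),
              attr(x, "provenance") %||% "unknown"))
  NextMethod()
}

#' Provenance tag of a topology or trajectory
#' @param x A `bir3_topology` or `bir3_trajectory`.
#' @return Character scalar.
#' @export
provenance <- function(x) {
  if (inherits(x, "bir3_trajectory")) return(attr(x$topology, "provenance"))
  attr(x, "provenance") %||% "unknown"
}

#' Coordinates of a topology as a matrix
#' @param top A `bir3_topology`.
#' @return `n_atoms x 3` numeric matrix (Angstrom).
#' @export
topology_coords <- function(top) {
  m <- cbind(top$x, top$y, top$z)
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}

#' Replace the coordinates of a topology
#' @param top A `bir3_topology`.
#' @param coords `n_atoms x 3` matrix.
#' @return The topology with new coordinates.
#' @export
set_coords <- function(top, coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(top) || ncol(coords) != 3) {
    abort("coords must be an n_atoms x 3 matrix")
  }
  top$x <- coords[, 1]; top$y <- coords[, 2]; top$z <- coords[, 3]
  top
}

#' Resolve an atom selection
#'
#' Selections are deterministic: the returned indices are always in
#' ascending atom order, and the same specification on the same topology
#' yields the same result.
#'
#' @param top A `bir3_topology`.
#' @param segment Optional `"receptor"` or `"ligand"`.
#' @param residues Optional integer vector of residue ids (paper numbering).
#' @param atom_names Optional atom-name filter; the shorthand `"backbone"`
#'   expands to N, CA, C, O.
#' @param hydrogens Keep hydrogen atoms? Default `TRUE`.
#' @return Integer vector of row indices into `top` (never empty).
#' @export
select_atoms <- function(top, segment = NULL, residues = NULL,
                         atom_names = NULL, hydrogens = TRUE) {
  keep <- rep(TRUE, nrow(top))
  if (!is.null(segment)) keep <- keep & top$segment %in% segment
  if (!is.null(residues)) keep <- keep & top$residue_id %in% residues
  if (!is.null(atom_names)) {
    if (identical(atom_names, "backbone")) atom_names <- .backbone_names
    keep <- keep & top$atom_name %in% atom_names
  }
  if (!hydrogens) keep <- keep & !top$is_hydrogen
  idx <- which(keep)
  if (length(idx) == 0) abort("selection resolved to an empty atom set")
  sort(idx)
}

#' Split a complex into receptor and ligand
#'
#' Implements the single-trajectory convention: the free receptor and free
#' ligand are obtained from a complex snapshot by removing the other
#' segment's atoms, so their conformations are exactly those of the complex
#' frame.
#'
#' @param top A `bir3_topology` containing both segments.
#' @param frame Optional `n_atoms x 3` coordinate matrix overriding the
#'   topology's own coordinates (e.g. a trajectory frame).
#' @return List with elements `receptor` and `ligand`, each a
#'   `bir3_topology` carrying the frame coordinates, plus `receptor_idx` and
#'   `ligand_idx` (row indices into the complex).
#' @export
split_complex <- function(top, frame = NULL) {
  if (!all(c("receptor", "ligand") %in% unique(top$segment))) {
    abort("split_complex needs a topology with both receptor and ligand atoms")
  }
  if (!is.null(frame)) top <- set_coords(top, frame)
  ridx <- which(top$segment == "receptor")
  lidx <- which(top$segment == "ligand")
  rec <- top[ridx, ]; lig <- top[lidx, ]
  attr(rec, "provenance") <- attr(top, "provenance")
  attr(lig, "provenance") <- attr(top, "provenance")
  class(rec) <- class(top); class(lig) <- class(top)
  list(receptor = rec, ligand = lig, receptor_idx = ridx, ligand_idx = lidx)
}

#' Construct a trajectory
#'
#' An ordered set of coordinate frames over a fixed topology; stands in for
#' an MD production trajectory (e.g. snapshots saved every 20 ps).
#'
#' @param topology A `bir3_topology`.
#' @param frames List of `n_atoms x 3` matrices (Angstrom).
#' @param frame_interval Time between frames, ps (> 0).
#' @param temperature Simulation temperature, K (> 0); default 303.15.
#' @return A `bir3_trajectory` object.
#' @export
new_trajectory <- function(topology, frames, frame_interval = 20,
                           temperature = 303.15) {
  if (!inherits(topology, "bir3_topology")) abort("topology must be a bir3_topology")
  if (length(frames) < 1) abort("a trajectory needs at least one frame")
  if (frame_interval <= 0) abort("frame_interval must be > 0")
  if (temperature <= 0) abort("temperature must be > 0")
  n <- nrow(topology)
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!is.matrix(f) || nrow(f) != n || ncol(f) != 3 || any(!is.finite(f))) {
      abort(sprintf("frame %d does not have %d finite coordinate triples", i, n))
    }
  }
  structure(list(topology = topology, frames = frames,
                 frame_interval = frame_interval, temperature = temperature),
            class = "bir3_trajectory")
}

#' @export
print.bir3_trajectory <- function(x, ...) {
  cat(sprintf("<bir3_trajectory> %d frames x %d atoms, dt = %g ps, T = %g K\n",
              length(x$frames), nrow(x$topology), x$frame_interval, x$temperature))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `bir3_trajectory`.
#' @return Integer.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Check that all atoms of a topology are parameterized
#' @keywords internal
.check_parameterized <- function(top, what = "this calculation") {
  bad <- which(!is.finite(top$charge) | !is.finite(top$lj_epsilon) |
                 !is.finite(top$lj_rmin_half) | !is.finite(top$mass))
  if (length(bad) > 0) {
    abort(sprintf("atoms not parameterized for %s: indices %s", what,
                  paste(utils::head(top$atom_index[bad], 10), collapse = ", ")))
  }
  invisible(TRUE)
}
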