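# Structural trajectory analyses: optimal superposition, core-backbone and
# ligand RMSD, hydrogen-bond occupancy, residue-ligand contact maps.


#' Default protein core: residues 259-335 when present (the XIAP-BIR3 core
#' between the flexible termini), otherwise every receptor residue.
#' @keywords internal
.default_core <- function(top) {
  present <- unique(top$residue_id[top$segment == "receptor"])
  core <- intersect(259:335, present)
  if (length(core) == 0) sort(present) else core
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rotation + translation mapping `mobile` onto `ref` over a
#' selection, via SVD of the covariance matrix with the usual determinant
#' correction so the rotation is proper (det = +1).
#'
#' @param ref_coords,mobile_coords `n x 3` matrices with matching rows.
#' @param selection Optional integer rows used for the fit (default all);
#'   must resolve to >= 3 non-collinear points.
#' @return List of class `bir3_superposition`: `rotation` (3x3),
#'   `translation` (length 3), `rmsd` (A over the fit selection).  The
#'   transform maps a mobile coordinate row-vector x to
#'   `x %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(ref_coords, mobile_coords, selection = NULL) {
  ref_coords <- as.matrix(ref_coords); mobile_coords <- as.matrix(mobile_coords)
  if (nrow(ref_coords) != nrow(mobile_coords)) {
    abort("ref and mobile coordinate sets differ in length")
  }
  sel <- selection %||% seq_len(nrow(ref_coords))
  if (length(sel) < 3) abort("superposition needs at least 3 points")
  A <- ref_coords[sel, , drop = FALSE]
  B <- mobile_coords[sel, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  sv <- svd(crossprod(B0, A0))   # 3x3 covariance
  if (sv$d[2] < 1e-10) abort("degenerate (collinear) selection for superposition")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  trans <- ca - as.numeric(cb %*% t(R))
  fitted <- B %*% t(R) + matrix(trans, nrow(B), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - A)^2)))
  structure(list(rotation = R, translation = trans, rmsd = rmsd),
            class = "bir3_superposition")
}

#' Apply a superposition transform to coordinates
#' @param sup A `bir3_superposition`.
#' @param coords `n x 3` matrix.
#' @return Transformed coordinates.
#' @export
apply_superposition <- function(sup, coords) {
  as.matrix(coords) %*% t(sup$rotation) +
    matrix(sup$translation, nrow(coords), 3, byrow = TRUE)
}

#' Core-backbone RMSD along a trajectory
#'
#' Each frame is superposed on the reference over the backbone atoms of the
#' protein core (default residues 259-335, i.e. excluding the flexible
#' N-terminus 248-258 and C-terminus 336-352), and the RMSD of that same
#' selection is reported per frame.
#'
#' @param traj A `bir3_trajectory`.
#' @param core_residues Integer residue ids of the core (default 259:335,
#'   intersected with the residues present; an explicit vector must be fully
#'   present or an error lists the missing ids).
#' @param reference Optional `n_atoms x 3` reference coordinates (default:
#'   first frame).
#' @return Tibble `frame`, `rmsd` (A) with `mean`/`sd` attributes.
#' @export
core_rmsd_series <- function(traj, core_residues = NULL, reference = NULL) {
  top <- traj$topology
  explicit <- !is.null(core_residues)
  core_residues <- core_residues %||% .default_core(top)
  if (explicit) {
    missing <- setdiff(core_residues, unique(top$residue_id))
    if (length(missing) > 0) {
      abort(paste0("core residues missing from topology: ",
                   paste(missing, collapse = ", ")))
    }
  }
  sel <- select_atoms(top, segment = "receptor", residues = core_residues,
                      atom_names = "backbone")
  ref <- reference %||% traj$frames[[1]]
  r <- vapply(traj$frames, function(f) {
    kabsch_superpose(ref, f, selection = sel)$rmsd
  }, numeric(1))
  out <- tibble(frame = seq_along(r), rmsd = r)
  attr(out, "mean") <- mean(r); attr(out, "sd") <- stats::sd(r)
  attr(out, "selection") <- sel
  out
}

#' Ligand RMSD after core alignment
#'
#' Each frame is first superposed on the reference over the protein-core
#' backbone (termini excluded); the resulting transform is applied to the
#' whole frame and the heavy-atom RMSD of the ligand against the reference
#' is reported.  Mean ligand RMSD above `unstable_threshold` (default 2 A)
#' is flagged as unstable binding.
#'
#' @inheritParams core_rmsd_series
#' @param unstable_threshold Mean-RMSD flag threshold, A.
#' @return Tibble `frame`, `rmsd`; attributes `mean`, `sd`, `unstable`.
#' @export
ligand_rmsd_series <- function(traj, core_residues = NULL, reference = NULL,
                               unstable_threshold = 2) {
  top <- traj$topology
  core_residues <- core_residues %||% .default_core(top)
  core_sel <- select_atoms(top, segment = "receptor", residues = core_residues,
                           atom_names = "backbone")
  lig_sel <- select_atoms(top, segment = "ligand", hydrogens = FALSE)
  ref <- reference %||% traj$frames[[1]]
  r <- vapply(traj$frames, function(f) {
    sup <- kabsch_superpose(ref, f, selection = core_sel)
    moved <- apply_superposition(sup, f[lig_sel, , drop = FALSE])
    sqrt(mean(rowSums((moved - ref[lig_sel, , drop = FALSE])^2)))
  }, numeric(1))
  out <- tibble(frame = seq_along(r), rmsd = r)
  attr(out, "mean") <- mean(r); attr(out, "sd") <- stats::sd(r)
  attr(out, "unstable") <- mean(r) > unstable_threshold
  if (attr(out, "unstable")) {
    warn(sprintf("mean ligand RMSD %.2f A exceeds %.1f A: unstable binding",
                 mean(r), unstable_threshold))
  }
  out
}

#' Hydrogen-bond criterion
#'
#' Geometric criterion: donor-acceptor distance below `max_distance`
#' (default 3.5 A) and, only when a hydrogen atom is supplied, a
#' donor-hydrogen-acceptor angle of at least `min_angle` degrees
#' (default 120).
#'
#' @param donor,acceptor Atom indices (`atom_index` values) of the donor
#'   heavy atom and the acceptor.
#' @param hydrogen Optional atom index of the donor hydrogen.
#' @param max_distance Maximum donor-acceptor distance, A.
#' @param min_angle Minimum D-H...A angle, degrees.
#' @return An `hbond_criterion` list.
#' @export
hbond_criterion <- function(donor, acceptor, hydrogen = NULL,
                            max_distance = 3.5, min_angle = 120) {
  if (max_distance <= 0) abort("max_distance must be > 0")
  if (min_angle < 0 || min_angle > 180) abort("min_angle must be in [0, 180]")
  structure(list(donor = donor, acceptor = acceptor, hydrogen = hydrogen,
                 max_distance = max_distance, min_angle = min_angle),
            class = "hbond_criterion")
}

#' Hydrogen-bond occupancy along a trajectory
#'
#' Fraction of frames in which the criterion holds.
#'
#' @param traj A `bir3_trajectory`.
#' @param criterion An [hbond_criterion()].
#' @return Occupancy in [0, 1]; attribute `n_frames_bonded`.
#' @export
hbond_occupancy <- function(traj, criterion) {
  stopifnot(inherits(criterion, "hbond_criterion"))
  top <- traj$topology
  di <- match(criterion$donor, top$atom_index)
  ai <- match(criterion$acceptor, top$atom_index)
  hi <- if (!is.null(criterion$hydrogen)) {
    match(criterion$hydrogen, top$atom_index)
  } else NA_integer_
  if (is.na(di) || is.na(ai) || (!is.null(criterion$hydrogen) && is.na(hi))) {
    abort("hbond criterion refers to atoms not present in the topology")
  }
  ok <- vapply(traj$frames, function(f) {
    d <- sqrt(sum((f[di, ] - f[ai, ])^2))
    if (d > criterion$max_distance) return(FALSE)
    if (!is.na(hi)) {
      v1 <- f[di, ] - f[hi, ]; v2 <- f[ai, ] - f[hi, ]
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
      if (ang < criterion$min_angle) return(FALSE)
    }
    TRUE
  }, logical(1))
  out <- mean(ok)
  attr(out, "n_frames_bonded") <- sum(ok)
  out
}

#' Residue-ligand contact map over a trajectory
#'
#' Entry (residue r, ligand atom a) is the fraction of frames in which any
#' heavy atom of residue r lies within `cutoff` of ligand atom a.
#'
#' @param traj A `bir3_trajectory`.
#' @param cutoff Heavy-atom distance cutoff, A (default 4.0).
#' @return Tidy tibble `residue_id`, `ligand_atom` (atom_index),
#'   `frequency` in [0, 1]; also carries a `matrix` attribute
#'   (residues x ligand atoms).
#' @export
contact_map <- function(traj, cutoff = 4.0) {
  if (cutoff <= 0) abort("cutoff must be > 0")
  top <- traj$topology
  rsel <- select_atoms(top, segment = "receptor", hydrogens = FALSE)
  lsel <- select_atoms(top, segment = "ligand", hydrogens = FALSE)
  res_ids <- sort(unique(top$residue_id[rsel]))
  counts <- matrix(0, length(res_ids), length(lsel),
                   dimnames = list(res_ids, top$atom_index[lsel]))
  for (f in traj$frames) {
    d <- .pair_distances(f[rsel, , drop = FALSE], f[lsel, , drop = FALSE])
    hit <- d <= cutoff
    byres <- rowsum(hit + 0, group = top$residue_id[rsel])
    counts <- counts + (byres[as.character(res_ids), , drop = FALSE] > 0)
  }
  freq <- counts / length(traj$frames)
  out <- as_tibble(as.data.frame.table(freq, stringsAsFactors = FALSE))
  names(out) <- c("residue_id", "ligand_atom", "frequency")
  out$residue_id <- as.integer(out$residue_id)
  out$ligand_atom <- as.integer(out$ligand_atom)
  attr(out, "matrix") <- freq
  attr(out, "cutoff") <- cutoff
  class(out) <- c("bir3_contact_map", class(out))
  out
}
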