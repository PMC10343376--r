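# Shared fixtures, all generated in code at test time.

# Reference 8-feature pharmacophore (2 HBD, 1 HBA, 4 H, 1 HAr), the same
# composition as the merged structure-based model, with one distant
# exclusion volume.  Distinct inter-feature distances keep assignment
# pruning effective.
ref_model8 <- function(tolerance = 1.5) {
  feats <- tibble::tibble(
    kind = c("HBD", "HBD", "HBA", "H", "H", "H", "H", "HAr"),
    x = c(0, 2.5, 1.2, -2.0, 4.5, 0.8, 3.2, -1.1),
    y = c(0, 0.8, 2.6, 1.5, -1.0, -2.8, 2.9, -2.2),
    z = c(0, 1.7, -0.9, 2.2, 1.1, 0.4, -1.8, -0.6),
    tolerance = tolerance)
  pharmacophore_model(feats,
                      tibble::tibble(x = 8, y = 8, z = 8, radius = 1.0),
                      name = "ref8")
}

# A minimal planted complex for model building: one receptor residue
# provides a backbone N (donor) and O (acceptor); the ligand has an
# acceptor O sitting 2.8 A from the receptor N, a donor N 2.8 A from the
# receptor O, and a 3-carbon chain cluster within 4 A of receptor heavy
# atoms.  All distances are deliberate so each perception/retention rule
# fires exactly once.
planted_complex <- function() {
  atoms <- tibble::tibble(
    atom_index = 1:9,
    atom_name = c("N", "CA", "C", "O", "OL", "NL", "C1", "C2", "C3"),
    residue_name = c(rep("ALA", 4), rep("LIG", 5)),
    residue_id = c(rep(300L, 4), rep(900L, 5)),
    x = c(0.0, 1.5, 2.9, 3.5, 0.0, 3.5, 1.0, 2.4, 1.7),
    y = c(0.0, 0.8, 0.0, -1.1, 2.8, -3.9, 3.3, 3.3, 4.4),
    z = rep(0, 9),
    charge = c(-0.3, 0.1, 0.45, -0.25, -0.3, 0.3, 0, 0, 0),
    lj_epsilon = rep(0.1, 9),
    lj_rmin_half = rep(1.9, 9),
    pb_radius = rep(1.7, 9),
    mass = c(14, 12, 12, 16, 16, 14, 12, 12, 12),
    is_hydrogen = FALSE,
    hbond_role = c("donor_heavy", "none", "none", "acceptor",
                   "acceptor", "donor_heavy", "none", "none", "none"),
    group_id = c(rep(NA, 4), "G1", "G1", "G2", "G2", "G2")
  )
  as_topology(atoms, provenance = "synthetic")
}

# Random parameterized two-segment topology for pairwise-oracle and
# partition property tests.
random_complex <- function(n_rec = 20, n_lig = 10, seed = 1) {
  set.seed(seed)
  n <- n_rec + n_lig
  # spread atoms so no pair overlaps
  crd <- matrix(runif(3 * n, 0, 25), ncol = 3)
  while (min(dist(crd)) < 1.2) crd <- matrix(runif(3 * n, 0, 25), ncol = 3)
  as_topology(tibble::tibble(
    atom_index = seq_len(n),
    atom_name = paste0("X", seq_len(n)),
    residue_name = c(rep("ALA", n_rec), rep("LIG", n_lig)),
    residue_id = c(rep(seq_len(ceiling(n_rec / 4)), each = 4)[seq_len(n_rec)],
                   rep(100L, n_lig)),
    x = crd[, 1], y = crd[, 2], z = crd[, 3],
    charge = round(runif(n, -0.5, 0.5), 3),
    lj_epsilon = runif(n, 0.05, 0.2),
    lj_rmin_half = runif(n, 1.6, 2.1),
    pb_radius = runif(n, 1.5, 2.0),
    mass = sample(c(12.011, 14.007, 15.999), n, replace = TRUE),
    is_hydrogen = FALSE,
    hbond_role = "none",
    group_id = c(rep(NA_character_, n_rec),
                 sample(c("G1", "G2"), n_lig, replace = TRUE))
  ), provenance = "synthetic")
}

# Brute-force O(n^2) interaction-energy oracle, written independently of
# the vectorized implementation.
brute_force_interaction <- function(top, frame = NULL) {
  if (!is.null(frame)) top <- set_coords(top, frame)
  rec <- top[top$segment == "receptor", ]
  lig <- top[top$segment == "ligand", ]
  elec <- 0; vdw <- 0
  for (i in seq_len(nrow(rec))) {
    for (j in seq_len(nrow(lig))) {
      dx <- rec$x[i] - lig$x[j]; dy <- rec$y[i] - lig$y[j]
      dz <- rec$z[i] - lig$z[j]
      r <- sqrt(dx^2 + dy^2 + dz^2)
      elec <- elec + 332.0636 * rec$charge[i] * lig$charge[j] / r
      eps <- sqrt(rec$lj_epsilon[i] * lig$lj_epsilon[j])
      rmin <- rec$lj_rmin_half[i] + lig$lj_rmin_half[j]
      vdw <- vdw + eps * ((rmin / r)^12 - 2 * (rmin / r)^6)
    }
  }
  list(elec = elec, vdw = vdw, e_inte = elec + vdw)
}

# Random rigid motion (proper rotation + translation) for invariance tests.
random_rigid_motion <- function(seed = 1) {
  set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  R <- matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
    2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
    2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
    1 - 2 * (q[2]^2 + q[3]^2)), 3, 3, byrow = TRUE)
  list(R = R, t = rnorm(3, 0, 5))
}

apply_rigid <- function(coords, motion) {
  coords %*% t(motion$R) + matrix(motion$t, nrow(coords), 3, byrow = TRUE)
}

# Small multi-model PDB written to a temp file.
write_fixture_pdb <- function(top, path, frames = NULL) {
  if (is.null(frames)) {
    write_structure(top, path)
  } else {
    traj <- new_trajectory(top, frames)
    write_structure(traj, path)
  }
  path
}
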