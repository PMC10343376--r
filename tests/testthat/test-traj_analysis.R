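test_that("Kabsch superposition recovers rigid motions and hand cases", {
  set.seed(1)
  ref <- matrix(rnorm(30), ncol = 3)
  sup0 <- kabsch_superpose(ref, ref)
  expect_equal(sup0$rmsd, 0, tolerance = 1e-12)
  expect_equal(sup0$rotation, diag(3), tolerance = 1e-9)
  mo <- random_rigid_motion(2)
  moved <- apply_rigid(ref, mo)
  sup <- kabsch_superpose(ref, moved)
  expect_lt(sup$rmsd, 1e-9)
  expect_equal(crossprod(sup$rotation), diag(3), tolerance = 1e-9)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-9)
  # 2-point sets are rejected (underdetermined), as are collinear sets
  expect_error(kabsch_superpose(ref[1:2, ], ref[1:2, ]), "3 points")
  lin <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(lin, lin + 1), "collinear")
  expect_error(kabsch_superpose(ref, ref[1:5, ]), "length")
})

test_that("optimal superposition never scores worse than no alignment", {
  for (seed in 1:5) {
    set.seed(seed)
    ref <- matrix(rnorm(45), ncol = 3)
    mob <- ref + matrix(rnorm(45, 0, 0.5), ncol = 3)
    aligned <- kabsch_superpose(ref, mob)$rmsd
    raw <- sqrt(mean(rowSums((mob - ref)^2)))
    expect_lte(aligned, raw + 1e-12)
  }
})

test_that("core RMSD is zero on frozen ensembles and after pure rigid motion", {
  top <- make_toy_complex(6, default_ligand_spec(1), seed = 1)
  frozen <- make_ensemble(ensemble_recipe(top, sigma = 0, n_frames = 5,
                                          seed = 0))
  expect_equal(core_rmsd_series(frozen)$rmsd, rep(0, 5), tolerance = 1e-9)
  # rigid-body motion only: rmsd vanishes after alignment
  base <- topology_coords(top)
  frames <- lapply(1:4, function(i) apply_rigid(base, random_rigid_motion(i)))
  traj <- new_trajectory(top, frames)
  expect_lt(max(core_rmsd_series(traj)$rmsd), 1e-9)
  expect_lt(max(ligand_rmsd_series(traj)$rmsd), 1e-9)
})

test_that("core RMSD against a noiseless reference tracks the planted jitter", {
  top <- make_toy_complex(30, default_ligand_spec(1), seed = 5)
  sigma <- 0.4
  traj <- make_ensemble(ensemble_recipe(top, sigma = sigma, n_frames = 60,
                                        seed = 8))
  r <- core_rmsd_series(traj, reference = topology_coords(top))
  # per-coordinate sd sigma in 3D, minus the 6 degrees of freedom the
  # superposition absorbs out of 3 * n_sel coordinates
  n_sel <- length(attr(r, "selection"))
  predicted <- sqrt(3) * sigma * sqrt(1 - 6 / (3 * n_sel))
  expect_lt(abs(attr(r, "mean") - predicted) / predicted, 0.15)
})

test_that("a rigidly displaced ligand reports its displacement and is flagged", {
  top <- make_toy_complex(6, default_ligand_spec(1), seed = 1)
  base <- topology_coords(top)
  shifted <- base
  lig <- top$segment == "ligand"
  shifted[lig, 1] <- shifted[lig, 1] + 3
  traj <- new_trajectory(top, list(base, shifted, shifted, shifted))
  expect_warning(r <- ligand_rmsd_series(traj), "unstable")
  expect_equal(r$rmsd, c(0, 3, 3, 3), tolerance = 1e-9)
  expect_true(attr(r, "unstable"))
})

test_that("hydrogen-bond occupancy honours distance and angle criteria", {
  top <- make_toy_complex(4, default_ligand_spec(1), seed = 3)
  don <- top$atom_index[top$hbond_role == "donor_heavy"][1]
  acc <- top$atom_index[top$segment == "ligand" &
                          top$hbond_role == "acceptor"][1]
  traj <- make_ensemble(ensemble_recipe(
    top, sigma = 0.1, n_frames = 100,
    hbond_schedules = list(list(donor = don, acceptor = acc,
                                occupancy = 0.6)), seed = 2))
  expect_equal(as.numeric(hbond_occupancy(traj, hbond_criterion(don, acc))),
               0.6)
  # a criterion that can never fire
  never <- hbond_criterion(don, acc, max_distance = 0.1)
  expect_equal(as.numeric(hbond_occupancy(traj, never)), 0)
  expect_error(hbond_occupancy(traj, hbond_criterion(9999L, acc)),
               "not present")
  expect_error(hbond_criterion(don, acc, max_distance = -1), "> 0")
})

test_that("the angle criterion applies only when a hydrogen is given", {
  # donor - hydrogen - acceptor nearly linear: angle ~ 180, passes;
  # bent arrangement (~90 deg) fails the 120-degree default
  atoms <- tibble::tibble(
    atom_index = 1:3, atom_name = c("N", "H", "O"),
    residue_name = c("ALA", "ALA", "LIG"), residue_id = c(1L, 1L, 2L),
    x = c(0, 1, 2.8), y = 0, z = 0,
    charge = 0, lj_epsilon = 0.1, lj_rmin_half = 1.8, pb_radius = 1.6,
    mass = c(14, 1, 16), is_hydrogen = c(FALSE, TRUE, FALSE),
    hbond_role = c("donor_heavy", "polar_h", "acceptor"),
    group_id = c(NA, NA, "G1"))
  top <- as_topology(atoms, provenance = "test")
  lin <- topology_coords(top)
  bent <- lin; bent[3, ] <- c(1, 1.8, 0)   # acceptor beside the hydrogen
  traj <- new_trajectory(top, list(lin, bent))
  with_h <- hbond_criterion(1L, 3L, hydrogen = 2L)
  expect_equal(as.numeric(hbond_occupancy(traj, with_h)), 0.5)
  no_h <- hbond_criterion(1L, 3L)
  expect_equal(as.numeric(hbond_occupancy(traj, no_h)), 1.0)
})

test_that("contact maps recover planted contact frequencies", {
  top <- make_toy_complex(4, default_ligand_spec(1), seed = 3)
  base <- topology_coords(top)
  lig <- top$segment == "ligand"
  away <- base; away[lig, 3] <- away[lig, 3] + 100
  # ligand in contact for 60 of 100 frames
  frames <- c(replicate(60, base, simplify = FALSE),
              replicate(40, away, simplify = FALSE))
  traj <- new_trajectory(top, frames)
  cm <- contact_map(traj, cutoff = 4.0)
  expect_true(all(cm$frequency >= 0 & cm$frequency <= 1))
  expect_setequal(unique(cm$frequency), c(0, 0.6))
  near_entry <- cm$frequency[cm$frequency > 0]
  expect_equal(unique(near_entry), 0.6)
  # all-distant ligand: all-zero map
  cm0 <- contact_map(new_trajectory(top, list(away)))
  expect_true(all(cm0$frequency == 0))
  # frozen ensemble: entries are 0 or 1
  cm1 <- contact_map(new_trajectory(top, list(base, base)))
  expect_true(all(cm1$frequency %in% c(0, 1)))
  expect_error(contact_map(traj, cutoff = -2), "> 0")
})

test_that("analyses are invariant under a uniform rigid motion of all frames", {
  top <- make_toy_complex(5, default_ligand_spec(1), seed = 6)
  traj <- make_ensemble(ensemble_recipe(top, sigma = 0.2, n_frames = 10,
                                        seed = 4))
  mo <- random_rigid_motion(9)
  moved <- new_trajectory(top, lapply(traj$frames, apply_rigid, motion = mo))
  expect_equal(core_rmsd_series(moved)$rmsd, core_rmsd_series(traj)$rmsd,
               tolerance = 1e-9)
  don <- top$atom_index[top$hbond_role == "donor_heavy"][1]
  acc <- top$atom_index[top$segment == "ligand" &
                          top$hbond_role == "acceptor"][1]
  crit <- hbond_criterion(don, acc)
  expect_equal(as.numeric(hbond_occupancy(moved, crit)),
               as.numeric(hbond_occupancy(traj, crit)))
  expect_equal(contact_map(moved)$frequency, contact_map(traj)$frequency)
})
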