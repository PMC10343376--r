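test_that("frame energy series counts frames according to the stride", {
  top <- make_toy_complex(3, default_ligand_spec(1), seed = 0)
  traj <- make_ensemble(ensemble_recipe(top, sigma = 0.05, n_frames = 10,
                                        seed = 1))
  ser <- frame_energy_series(traj, stride = 1, spacing = 1.0)
  expect_equal(nrow(ser), 10)
  ser5 <- frame_energy_series(traj, stride = 5, spacing = 1.0)
  expect_equal(ser5$frame, c(1, 6))
  expect_equal(ser$total, ser$e_inte + ser$g_polar + ser$g_nonpolar,
               tolerance = 1e-12)
})

test_that("a frozen ensemble yields identical frame energies and sd 0", {
  top <- make_toy_complex(3, default_ligand_spec(1), seed = 0)
  traj <- make_ensemble(ensemble_recipe(top, sigma = 0, n_frames = 4, seed = 0))
  ser <- frame_energy_series(traj, spacing = 1.0)
  expect_equal(ser$total, rep(ser$total[1], 4))
  est <- estimate_binding(ser)
  expect_equal(est$sd, 0)
  # single-frame value equals the ensemble mean
  one <- frame_energy_series(
    make_ensemble(ensemble_recipe(top, sigma = 0, n_frames = 1, seed = 0)),
    spacing = 1.0)
  expect_equal(est$dg, estimate_binding(one)$dg, tolerance = 1e-9)
  # stride invariance on frozen ensembles
  est2 <- estimate_binding(frame_energy_series(traj, stride = 2, spacing = 1.0))
  expect_equal(est2$dg, est$dg, tolerance = 1e-9)
})

test_that("binding estimate assembles components and entropy per the model", {
  mk <- function(totals, elec = totals, vdw = 0) {
    tibble::tibble(frame = seq_along(totals), elec = elec, vdw = vdw,
                   e_inte = elec + vdw, g_polar = 0, g_nonpolar = 0,
                   total = elec + vdw)
  }
  # constant frames: E = -50, polar = +20, nonpolar = -5
  ser <- tibble::tibble(frame = 1:3, elec = -50, vdw = 0, e_inte = -50,
                        g_polar = 20, g_nonpolar = -5, total = -35)
  expect_equal(estimate_binding(ser)$dg, -35)
  fake_ent <- structure(list(minus_T_dS = 10, method = "IE",
                             temperature = 303.15, n_samples = 3,
                             sigma = 1), class = "bir3_entropy")
  est <- estimate_binding(ser, fake_ent)
  expect_equal(est$dg, -25)
  expect_equal(sum(est$components) + est$entropy_term, est$dg,
               tolerance = 1e-9)
  # two frames at -30 and -40: mean -35, population sd 5
  est2 <- estimate_binding(mk(c(-30, -40)))
  expect_equal(est2$dg, -35)
  expect_equal(est2$sd, 5)
  expect_match(est2$sd_convention, "population")
  expect_error(estimate_binding(ser[0, ]), "empty")
  # tidy/glance round out the broom interface
  td <- tidy(est)
  expect_equal(td$estimate[td$term == "dG"], -25)
  expect_equal(glance(est)$entropy_method, "IE")
})

test_that("residue-wise interaction decomposition conserves the total", {
  for (seed in 1:3) {
    top <- random_complex(16, 6, seed = seed)
    traj <- new_trajectory(top, list(topology_coords(top)))
    dec <- per_residue_decomposition(traj, include_solvation = FALSE)
    tot <- interaction_energy(top)
    expect_equal(sum(dec$e_inte), tot$e_inte, tolerance = 1e-6)
    expect_equal(sum(dec$elec), tot$elec, tolerance = 1e-9)
  }
})

test_that("a residue far from the ligand contributes nothing", {
  top <- make_toy_complex(12, default_ligand_spec(1), seed = 0)
  # drag the first residue 100 A away
  crd <- topology_coords(top)
  first <- top$residue_id == min(top$residue_id)
  crd[first, 3] <- crd[first, 3] + 100
  traj <- new_trajectory(set_coords(top, crd), list(crd))
  dec <- per_residue_decomposition(traj, include_solvation = FALSE)
  far_row <- dec[dec$residue_id == min(top$residue_id), ]
  expect_lt(abs(far_row$e_inte), 0.05)
})

test_that("solvation-attributed rows sum to the undecomposed binding terms", {
  top <- make_toy_complex(3, default_ligand_spec(1), seed = 2)
  traj <- make_ensemble(ensemble_recipe(top, sigma = 0.05, n_frames = 2,
                                        seed = 3))
  dec <- per_residue_decomposition(traj, include_solvation = TRUE,
                                   spacing = 1.0)
  ser <- frame_energy_series(traj, spacing = 1.0)
  expect_equal(sum(dec$total) + attr(dec, "offset_row"), mean(ser$total),
               tolerance = 1e-6)
  # polar rows (minus the residue-ligand Coulomb part) sum to dG_polar
  expect_equal(sum(dec$polar) - sum(dec$elec), mean(ser$g_polar),
               tolerance = 1e-9)
})

test_that("group decomposition partitions e_inte and the cross matrix books balance", {
  top <- make_toy_complex(6, default_ligand_spec(3), seed = 1)
  traj <- make_ensemble(ensemble_recipe(top, sigma = 0.05, n_frames = 3,
                                        seed = 2))
  pg <- per_group_decomposition(traj)
  ser_e <- vapply(traj$frames, function(f) {
    interaction_energy(top, f)$e_inte
  }, numeric(1))
  expect_equal(sum(pg$groups$e_inte), mean(ser_e), tolerance = 1e-6)
  # cross matrix row sums equal group totals
  cm <- attr(pg$cross, "full_matrix")
  expect_equal(unname(rowSums(cm)),
               pg$groups$e_inte[match(rownames(cm), pg$groups$group_id)],
               tolerance = 1e-9)
  # single-group ligand: group row equals the total
  top1 <- make_toy_complex(4, default_ligand_spec(1), seed = 1)
  traj1 <- new_trajectory(top1, list(topology_coords(top1)))
  pg1 <- per_group_decomposition(traj1)
  expect_equal(pg1$groups$e_inte, interaction_energy(top1)$e_inte,
               tolerance = 1e-9)
  # untagged ligand atoms are an error
  bad <- top1
  bad$group_id[bad$segment == "ligand"][1] <- NA
  expect_error(per_group_decomposition(new_trajectory(bad, list(topology_coords(bad)))),
               "group_id")
})
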