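test_that("Coulomb energy matches hand arithmetic and scales with dielectric", {
  mk <- function(q, x) as_topology(tibble::tibble(
    atom_index = 1L, atom_name = "X", residue_name = "ION", residue_id = 1L,
    x = x, y = 0, z = 0, charge = q, lj_epsilon = 0.1, lj_rmin_half = 2,
    pb_radius = 1.5, mass = 12, is_hydrogen = FALSE, hbond_role = "none",
    segment = "ligand"), provenance = "test")
  a <- mk(1, 0); b <- mk(-1, 3.320636)
  expect_equal(coulomb_energy(a, b), -100.0, tolerance = 1e-9)
  expect_equal(coulomb_energy(mk(0, 0), b), 0)
  expect_equal(coulomb_energy(a, b, dielectric = 2), -50.0, tolerance = 1e-9)
  too_close <- mk(-1, 1e-8)
  expect_error(coulomb_energy(a, too_close), "overlapping")
})

test_that("LJ energy has its minimum at rmin and decays", {
  mk <- function(x, eps = 0.1, rmh = 2.0) as_topology(tibble::tibble(
    atom_index = 1L, atom_name = "X", residue_name = "ION", residue_id = 1L,
    x = x, y = 0, z = 0, charge = 0, lj_epsilon = eps, lj_rmin_half = rmh,
    pb_radius = 1.5, mass = 12, is_hydrogen = FALSE, hbond_role = "none",
    segment = "ligand"), provenance = "test")
  # two identical atoms eps=0.1, rmin_half=2.0 at r = rmin = 4.0 -> -eps
  expect_equal(lj_energy(mk(0), mk(4.0)), -0.1, tolerance = 1e-12)
  # mixed pair at the combined minimum
  a <- mk(0, eps = 0.2, rmh = 1.8); b <- mk(3.9, eps = 0.05, rmh = 2.1)
  expect_equal(lj_energy(a, b), -sqrt(0.2 * 0.05), tolerance = 1e-12)
  # decay: at 10x rmin the energy is vanishing
  expect_lt(abs(lj_energy(mk(0), mk(40))), 1e-4 * 0.1)
})

test_that("interaction energy equals the brute-force pairwise oracle", {
  for (seed in 1:4) {
    top <- random_complex(30, 12, seed = seed)
    got <- interaction_energy(top)
    want <- brute_force_interaction(top)
    expect_equal(got$elec, want$elec, tolerance = 1e-9)
    expect_equal(got$vdw, want$vdw, tolerance = 1e-9)
    expect_equal(got$e_inte, got$elec + got$vdw, tolerance = 1e-12)
  }
})

test_that("interaction energy vanishes for a far-separated ligand", {
  # net-neutral ligand: the residual multipole tail decays fast
  top <- make_toy_complex(3, default_ligand_spec(1, group_charges = 0),
                          seed = 0)
  crd <- topology_coords(top)
  crd[top$segment == "ligand", 1] <- crd[top$segment == "ligand", 1] + 100
  ee <- interaction_energy(top, crd)
  expect_lt(abs(ee$e_inte), 1e-3)
})

test_that("MM energies are invariant under rigid motion", {
  top <- random_complex(15, 8, seed = 7)
  e0 <- interaction_energy(top)
  for (seed in 1:3) {
    mo <- random_rigid_motion(seed)
    e1 <- interaction_energy(top, apply_rigid(topology_coords(top), mo))
    expect_equal(e1$e_inte, e0$e_inte, tolerance = 1e-6)
  }
})

test_that("SASA reproduces the isolated-sphere and two-sphere closed forms", {
  mk <- function(n, coords, r) as_topology(tibble::tibble(
    atom_index = seq_len(n), atom_name = "X", residue_name = "ION",
    residue_id = 1L, x = coords[, 1], y = coords[, 2], z = coords[, 3],
    charge = 0, lj_epsilon = 0, lj_rmin_half = 2, pb_radius = r, mass = 12,
    is_hydrogen = FALSE, hbond_role = "none", segment = "ligand"),
    provenance = "test")
  # isolated atom radius 1.9, probe 1.4 -> 4 pi 3.3^2
  one <- mk(1, matrix(0, 1, 3), 1.9)
  expect_equal(sasa_total(one), 4 * pi * 3.3^2, tolerance = 0.01 * 4 * pi * 3.3^2)
  # two distant atoms: additivity
  two_far <- mk(2, rbind(c(0, 0, 0), c(100, 0, 0)), 1.9)
  expect_equal(sasa_total(two_far), 2 * 4 * pi * 3.3^2,
               tolerance = 0.01 * 8 * pi * 3.3^2)
  # two equal spheres R = 2.0 + 1.4 at d = 3.0: spherical-cap closed form
  R <- 3.4; d <- 3.0
  closed <- 2 * (4 * pi * R^2 - 2 * pi * R * (R - d / 2))
  two_close <- mk(2, rbind(c(0, 0, 0), c(d, 0, 0)), 2.0)
  expect_equal(sasa_total(two_close), closed, tolerance = 0.01 * closed)
  expect_error(sasa(one, n_sphere_points = 10), ">= 24")
})

test_that("SASA shrinks as atoms approach and is rotation invariant", {
  top <- random_complex(10, 5, seed = 3)
  s0 <- sasa_total(top)
  mo <- random_rigid_motion(4)
  rot <- set_coords(top, apply_rigid(topology_coords(top), mo))
  expect_equal(sasa_total(rot), s0, tolerance = 0.01 * s0)
  # move atom 2 to 60% of its distance from atom 1; area must not increase
  crd2 <- topology_coords(top)
  crd2[2, ] <- crd2[1, ] + 0.6 * (crd2[2, ] - crd2[1, ])
  s1 <- sasa_total(set_coords(top, crd2))
  expect_lte(s1, s0 + 1e-6)
})

test_that("the non-polar SASA model is the stated linear form", {
  expect_equal(nonpolar_solvation(0), 0.92)
  expect_equal(nonpolar_solvation(1000), 6.34)
  # through the binding difference with SASAs 5000/4000/1500
  dG <- nonpolar_solvation(5000) - nonpolar_solvation(4000) -
    nonpolar_solvation(1500)
  expect_equal(dG, 0.00542 * (-500) - 0.92, tolerance = 1e-12)
  expect_equal(dG, -3.63, tolerance = 1e-12)
  expect_error(nonpolar_solvation(-5), ">= 0")
})

test_that("FD-PB reproduces the Born closed form", {
  b <- make_born_system(1, 2)
  exact <- -(332.0636 / 2) * (1 / 2) * (1 - 1 / 80)
  g04 <- pb_polar_energy(b, spacing = 0.4, ionic_strength = 0)
  expect_lt(abs(g04 - exact) / abs(exact), 0.02)
  g08 <- pb_polar_energy(b, spacing = 0.8, ionic_strength = 0)
  expect_lt(abs(g08 - exact) / abs(exact), 0.05)
})

test_that("PB energy is even in q, zero for q = 0, and shrinks with radius", {
  gp <- pb_polar_energy(make_born_system(1, 1.5), spacing = 0.8,
                        ionic_strength = 0)
  gm <- pb_polar_energy(make_born_system(-1, 1.5), spacing = 0.8,
                        ionic_strength = 0)
  expect_equal(gp, gm, tolerance = 1e-9)
  expect_equal(pb_polar_energy(make_born_system(0, 2), spacing = 0.8), 0)
  radii <- c(1.5, 2.0, 3.0)
  gs <- vapply(radii, function(a) {
    pb_polar_energy(make_born_system(1, a), spacing = 0.8,
                    ionic_strength = 0)
  }, numeric(1))
  expect_true(all(diff(abs(gs)) < 0))
})

test_that("PB with eps_out = eps_in gives zero within solver tolerance", {
  b <- make_born_system(1, 2)
  g <- pb_polar_energy(b, eps_in = 1, eps_out = 1, spacing = 0.8,
                       ionic_strength = 0)
  expect_lt(abs(g), 1e-6)
})

test_that("PB energy is invariant under translation within grid tolerance", {
  b <- make_born_system(1, 2)
  g0 <- pb_polar_energy(b, spacing = 0.5, ionic_strength = 0)
  shifted <- set_coords(b, matrix(c(0.21, -0.13, 0.34), 1, 3))
  g1 <- pb_polar_energy(shifted, spacing = 0.5, ionic_strength = 0)
  expect_lt(abs(g1 - g0) / abs(g0), 0.01)
})

test_that("solvation binding terms follow the three-solve difference scheme", {
  # neutral ligand far from the receptor: dG_polar ~ 0 and dG_nonpolar
  # reduces to the intercept convention (-0.92 from per-species intercepts)
  top <- make_toy_complex(2, default_ligand_spec(1), seed = 5)
  top$charge[top$segment == "ligand"] <- 0
  crd <- topology_coords(top)
  crd[top$segment == "ligand", 1] <- crd[top$segment == "ligand", 1] + 100
  sv <- solvation_binding_terms(top, crd, spacing = 0.8)
  expect_lt(abs(sv$g_polar), 0.3)        # grid noise only
  dsasa <- sv$sasa_complex - sv$sasa_receptor - sv$sasa_ligand
  expect_lt(abs(dsasa), 1)               # far apart: additive SASA
  expect_equal(sv$g_nonpolar, 0.00542 * dsasa - 0.92, tolerance = 1e-9)
})
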