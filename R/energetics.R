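# Molecular-mechanics interaction energies and solvation terms.
# All energies kcal/mol, distances Angstrom, charges e.

#' @keywords internal
.pair_distances <- function(ca, cb) {
  # |a_i - b_j| for all pairs; ca n x 3, cb m x 3
  d2 <- outer(rowSums(ca^2), rowSums(cb^2), "+") - 2 * (ca %*% t(cb))
  sqrt(pmax(d2, 0))
}

#' Coulomb interaction energy between two atom sets
#'
#' Exact pair sum \eqn{E = \sum_{ij} C q_i q_j / (\epsilon r_{ij})} with
#' C = 332.0636 kcal A/(mol e^2); no cutoff is applied (post-processing
#' convention; exact pair sums are cheap at desk scale).
#'
#' @param atoms_a,atoms_b `bir3_topology` subsets (disjoint atom sets) with
#'   charges set.
#' @param dielectric Relative dielectric constant, >= 1 (default 1, the
#'   vacuum value used throughout the MM-PBSA post-processing).
#' @return Energy in kcal/mol.
#' @export
coulomb_energy <- function(atoms_a, atoms_b, dielectric = 1) {
  if (dielectric < 1) abort("dielectric must be >= 1")
  if (any(!is.finite(atoms_a$charge)) || any(!is.finite(atoms_b$charge))) {
    abort("all charges must be set for coulomb_energy")
  }
  r <- .pair_distances(topology_coords(atoms_a), topology_coords(atoms_b))
  if (any(r < 1e-6)) abort("overlapping atoms (r < 1e-6 A) in coulomb_energy")
  .const$coulomb / dielectric * sum(outer(atoms_a$charge, atoms_b$charge) / r)
}

#' Lennard-Jones interaction energy between two atom sets
#'
#' CHARMM-form 12-6 potential with Lorentz-Berthelot-style combining:
#' \eqn{\epsilon_{ij} = \sqrt{\epsilon_i \epsilon_j}}, \eqn{r_{min,ij} =
#' r_{min,i}/2 + r_{min,j}/2}; \eqn{E = \sum \epsilon_{ij} [ (r_{min}/r)^{12}
#' - 2 (r_{min}/r)^6 ]}.  No cutoff.
#'
#' @inheritParams coulomb_energy
#' @return Energy in kcal/mol.
#' @export
lj_energy <- function(atoms_a, atoms_b) {
  if (any(!is.finite(atoms_a$lj_epsilon)) || any(!is.finite(atoms_b$lj_epsilon))) {
    abort("all LJ parameters must be set for lj_energy")
  }
  r <- .pair_distances(topology_coords(atoms_a), topology_coords(atoms_b))
  if (any(r < 1e-6)) abort("overlapping atoms (r < 1e-6 A) in lj_energy")
  epsij <- sqrt(outer(atoms_a$lj_epsilon, atoms_b$lj_epsilon))
  rmin <- outer(atoms_a$lj_rmin_half, atoms_b$lj_rmin_half, "+")
  s6 <- (rmin / r)^6
  sum(epsij * (s6^2 - 2 * s6))
}

#' Receptor-ligand molecular-mechanics interaction energy
#'
#' Electrostatic and van der Waals energies between the receptor and
#' ligand atom sets of a complex (no intra-segment terms), at the vacuum
#' dielectric.  This is the E_inte term of the MM-PBSA decomposition.
#'
#' @param top Parameterized `bir3_topology` with both segments.
#' @param frame Optional coordinate matrix overriding topology coordinates.
#' @return A one-row tibble with columns `elec`, `vdw`, `e_inte` (kcal/mol).
#' @export
interaction_energy <- function(top, frame = NULL) {
  .check_parameterized(top, "interaction_energy")
  sp <- split_complex(top, frame)
  elec <- coulomb_energy(sp$receptor, sp$ligand, dielectric = 1)
  vdw <- lj_energy(sp$receptor, sp$ligand)
  tibble(elec = elec, vdw = vdw, e_inte = elec + vdw)
}

#' @keywords internal
.sphere_points <- function(n) {
  # deterministic golden-spiral quadrature points on the unit sphere
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom SASA with a rolling probe, computed by deterministic
#' golden-spiral quadrature on each atom's solvent-accessible sphere
#' (radius `pb_radius + probe_radius`).
#'
#' @param top `bir3_topology` with `pb_radius` set for all included atoms.
#' @param frame Optional coordinate override.
#' @param probe_radius Probe radius in Angstrom (default 1.4, water).
#' @param n_sphere_points Quadrature points per atom (default 480; must be
#'   >= 24 for acceptable accuracy).
#' @param include_hydrogens Include hydrogens in the surface (default
#'   `FALSE`, heavy-atom surface).
#' @return Tibble with `atom_index` and `sasa` (A^2); total in attribute
#'   `total`, also returned by [sasa_total()].
#' @export
sasa <- function(top, frame = NULL, probe_radius = 1.4,
                 n_sphere_points = 480, include_hydrogens = FALSE) {
  if (n_sphere_points < 24) abort("n_sphere_points must be >= 24")
  if (!is.null(frame)) top <- set_coords(top, frame)
  if (!include_hydrogens) top <- top[!top$is_hydrogen, , drop = FALSE]
  if (any(!is.finite(top$pb_radius)) || any(top$pb_radius <= 0)) {
    abort("pb_radius must be set and > 0 for all atoms included in SASA")
  }
  n <- nrow(top)
  coords <- cbind(top$x, top$y, top$z)
  rad <- top$pb_radius + probe_radius
  pts <- .sphere_points(n_sphere_points)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    ri <- rad[i]
    test <- sweep(pts * ri, 2, coords[i, ], "+")
    # neighbours whose accessible spheres can overlap atom i's
    d <- sqrt(colSums((t(coords) - coords[i, ])^2))
    nb <- which(d < ri + rad & seq_len(n) != i)
    exposed <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      dj2 <- colSums((t(test) - coords[j, ])^2)
      exposed <- exposed & dj2 > rad[j]^2
      if (!any(exposed)) break
    }
    areas[i] <- 4 * pi * ri^2 * sum(exposed) / n_sphere_points
  }
  out <- tibble(atom_index = top$atom_index, sasa = areas)
  attr(out, "total") <- sum(areas)
  out
}

#' Total SASA of a topology
#' @inheritParams sasa
#' @return Total solvent-accessible surface area, A^2.
#' @export
sasa_total <- function(top, frame = NULL, probe_radius = 1.4,
                       n_sphere_points = 480) {
  attr(sasa(top, frame, probe_radius, n_sphere_points), "total")
}

#' Non-polar solvation free energy from SASA
#'
#' Linear SASA model `G = 0.00542 * SASA + 0.92` (kcal/mol, SASA in A^2).
#'
#' @param sasa_total Total SASA, A^2 (>= 0).
#' @param slope,intercept Coefficients of the linear model; defaults
#'   0.00542 kcal/mol/A^2 and 0.92 kcal/mol.
#' @return Energy in kcal/mol.
#' @export
nonpolar_solvation <- function(sasa_total, slope = 0.00542, intercept = 0.92) {
  if (any(sasa_total < 0)) abort("SASA must be >= 0")
  slope * sasa_total + intercept
}

#' Debye screening parameter from ionic strength
#' @param ionic_strength mol/L (1:1 salt).
#' @param eps_out Solvent dielectric.
#' @param temperature K.
#' @return kappa in 1/Angstrom.
#' @export
debye_kappa <- function(ionic_strength, eps_out = 80, temperature = 303.15) {
  if (ionic_strength <= 0) return(0)
  n <- 2 * ionic_strength * .const$avogadro_per_litre  # ions/A^3, both species
  sqrt(4 * pi * .const$coulomb * n / (eps_out * .const$R_gas * temperature))
}

#' Polar solvation free energy by finite-difference Poisson-Boltzmann
#'
#' Electrostatic solvation (reaction-field charging) free energy: the
#' linearized PB equation is solved twice on the identical grid -- once with
#' the solvent dielectric and Debye screening outside the van der Waals
#' surface, once in a uniform `eps_in` medium -- and the grid self-energy
#' cancels in the difference:
#' \eqn{G_{polar} = 1/2 \sum_i q_i [\phi_{solv}(r_i) - \phi_{ref}(r_i)]}.
#'
#' @param top Parameterized `bir3_topology` (or subset) with charges and
#'   `pb_radius` set.
#' @param frame Optional coordinate override.
#' @param eps_in Solute dielectric (default 1, vacuum).
#' @param eps_out Solvent dielectric (default 80).
#' @param ionic_strength 1:1 salt concentration, mol/L (default 0.15).
#' @param spacing Grid spacing, A (default 0.5; must be <= 1).
#' @param padding Grid padding beyond the solute bounding box, A
#'   (default 10, minimum 8).
#' @param grid Optional precomputed grid spec from [pb_grid_spec()]; when
#'   given, `spacing`/`padding` are ignored.  Use one shared spec for the
#'   complex/receptor/ligand solves of a binding calculation.
#' @param tol Relative residual tolerance (default 1e-6).
#' @param max_iter Maximum SOR iterations (default 20000).
#' @param details Return per-atom reaction-field potentials too?
#' @return Energy in kcal/mol, or a list with `g_polar`, `phi_rf` (per-atom
#'   reaction-field potential, kcal/mol/e), `grid`, `iterations` when
#'   `details = TRUE`.
#' @export
pb_polar_energy <- function(top, frame = NULL, eps_in = 1, eps_out = 80,
                            ionic_strength = 0.15, spacing = 0.5,
                            padding = 10, grid = NULL, tol = 1e-6,
                            max_iter = 20000L, details = FALSE) {
  if (!is.null(frame)) top <- set_coords(top, frame)
  heavy_bad <- !top$is_hydrogen & (!is.finite(top$pb_radius) | top$pb_radius <= 0)
  if (any(!is.finite(top$charge)) || any(heavy_bad)) {
    abort("charges and pb_radius must be set for pb_polar_energy")
  }
  if (is.null(grid)) grid <- pb_grid_spec(top, spacing = spacing, padding = padding)
  coords <- topology_coords(top)
  radii <- ifelse(is.finite(top$pb_radius) & top$pb_radius > 0,
                  top$pb_radius, 0.0)
  kappa <- debye_kappa(ionic_strength, eps_out = eps_out)
  omega <- 2 / (1 + sin(pi / max(grid$dims)))
  solv <- .fd_pb_solve(grid$dims, grid$origin, grid$spacing, coords,
                       top$charge, radii, eps_in, eps_out, kappa,
                       as.integer(max_iter), tol, omega)
  ref <- .fd_pb_solve(grid$dims, grid$origin, grid$spacing, coords,
                      top$charge, radii, eps_in, eps_in, 0,
                      as.integer(max_iter), tol, omega)
  phi_rf <- solv$phi_at_atoms - ref$phi_at_atoms
  g <- 0.5 * sum(top$charge * phi_rf)
  if (!details) return(g)
  list(g_polar = g, phi_rf = phi_rf, grid = grid,
       iterations = c(solvent = solv$iterations, reference = ref$iterations))
}

#' Build a PB grid specification
#'
#' The grid encloses the solute bounding box plus `padding` on every side;
#' node counts are chosen so the spacing is exactly `spacing`.
#'
#' @param top `bir3_topology` (coordinates + pb_radius define the extent).
#' @param spacing Grid spacing, A (<= 1).
#' @param padding Padding, A (>= 8).
#' @return List with `origin`, `spacing`, `dims`.
#' @export
pb_grid_spec <- function(top, spacing = 0.5, padding = 10) {
  if (spacing <= 0 || spacing > 1) abort("grid spacing must be in (0, 1] A")
  if (padding < 8) abort("grid padding must be >= 8 A")
  coords <- topology_coords(top)
  rad <- ifelse(is.finite(top$pb_radius), top$pb_radius, 0)
  lo <- apply(coords - rad, 2, min) - padding
  hi <- apply(coords + rad, 2, max) + padding
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  # centre the grid on the solute
  span <- (dims - 1L) * spacing
  centre <- (lo + hi) / 2
  list(origin = as.numeric(centre - span / 2), spacing = spacing, dims = dims)
}

#' Solvation contributions to binding (polar and non-polar)
#'
#' Three PB solves and three SASA evaluations (complex, receptor alone,
#' ligand alone, all extracted from the same complex frame and solved on an
#' identical grid spec), differenced:
#' \deqn{\Delta G_{polar} = G^{PB}_{complex} - G^{PB}_{receptor} - G^{PB}_{ligand}}
#' \deqn{\Delta G_{nonpolar} = G^{SASA}_{complex} - G^{SASA}_{receptor} - G^{SASA}_{ligand}}
#' The SASA-linear intercept is applied per species (literal reading of the
#' difference scheme), which contributes a constant -0.92 kcal/mol to
#' \eqn{\Delta G_{nonpolar}}; the convention is recorded in the output.
#'
#' @param top Parameterized complex topology.
#' @param frame Optional coordinate override.
#' @param spacing,padding,eps_in,eps_out,ionic_strength PB settings, see
#'   [pb_polar_energy()].
#' @param n_sphere_points SASA quadrature points.
#' @param details Return per-atom attributions (reaction-field and SASA
#'   differences) for decomposition?
#' @return One-row tibble `g_polar`, `g_nonpolar`, `sasa_complex`,
#'   `sasa_receptor`, `sasa_ligand`, `intercept_convention`; with
#'   `details = TRUE` a list also carrying per-atom attribution vectors.
#' @export
solvation_binding_terms <- function(top, frame = NULL, spacing = 0.5,
                                    padding = 10, eps_in = 1, eps_out = 80,
                                    ionic_strength = 0.15,
                                    n_sphere_points = 480, details = FALSE) {
  sp <- split_complex(top, frame)
  if (!is.null(frame)) top <- set_coords(top, frame)
  grid <- pb_grid_spec(top, spacing = spacing, padding = padding)
  pbc <- pb_polar_energy(top, grid = grid, eps_in = eps_in, eps_out = eps_out,
                         ionic_strength = ionic_strength, details = TRUE)
  pbr <- pb_polar_energy(sp$receptor, grid = grid, eps_in = eps_in,
                         eps_out = eps_out, ionic_strength = ionic_strength,
                         details = TRUE)
  pbl <- pb_polar_energy(sp$ligand, grid = grid, eps_in = eps_in,
                         eps_out = eps_out, ionic_strength = ionic_strength,
                         details = TRUE)
  sc <- sasa(top, n_sphere_points = n_sphere_points)
  sr <- sasa(sp$receptor, n_sphere_points = n_sphere_points)
  sl <- sasa(sp$ligand, n_sphere_points = n_sphere_points)
  g_polar <- pbc$g_polar - pbr$g_polar - pbl$g_polar
  g_np <- nonpolar_solvation(attr(sc, "total")) -
    nonpolar_solvation(attr(sr, "total")) -
    nonpolar_solvation(attr(sl, "total"))
  out <- tibble(
    g_polar = g_polar, g_nonpolar = g_np,
    sasa_complex = attr(sc, "total"), sasa_receptor = attr(sr, "total"),
    sasa_ligand = attr(sl, "total"),
    intercept_convention = "per-species (net -0.92 kcal/mol offset)"
  )
  if (!details) return(out)
  # per-atom attributions (complex ordering)
  n <- nrow(top)
  phi_species <- numeric(n)
  phi_species[sp$receptor_idx] <- pbr$phi_rf
  phi_species[sp$ligand_idx] <- pbl$phi_rf
  polar_atom <- 0.5 * top$charge * (pbc$phi_rf - phi_species)
  sasa_species <- setNames(rep(0, n), top$atom_index)
  sasa_complexv <- setNames(rep(0, n), top$atom_index)
  sasa_complexv[as.character(sc$atom_index)] <- sc$sasa
  sasa_species[as.character(sr$atom_index)] <- sr$sasa
  sasa_species[as.character(sl$atom_index)] <- sl$sasa
  list(summary = out, polar_atom = polar_atom,
       dsasa_atom = unname(sasa_complexv - sasa_species), grid = grid)
}
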