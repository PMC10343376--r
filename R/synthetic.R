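# Seeded synthetic-data generators.  These produce every input the pipeline
# needs -- toy protein-ligand complexes, fluctuating ensembles with planted
# hydrogen-bond schedules, Gaussian interaction-energy series, Born ions,
# and labelled screening libraries -- so all stages are testable without MD
# engines or external downloads.  All generators are pure functions of
# (recipe, seed).

#' Evaluate code with a temporary RNG seed
#' @keywords internal
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Default ligand specification for toy complexes
#'
#' A small multi-group ligand mimicking the layout of a BIR3 groove binder:
#' each group is a rigid cluster of parameterized pseudo-atoms with its own
#' net charge and hydrogen-bonding roles.
#'
#' @param n_groups Number of ligand groups (1-5), tagged G1..Gk.
#' @param group_charges Optional numeric vector of per-group net charges
#'   (recycled); default gives G1 charge +0.4, the rest alternating small
#'   charges.
#' @return List of group definitions consumable by [make_toy_complex()].
#' @export
default_ligand_spec <- function(n_groups = 2, group_charges = NULL) {
  if (n_groups < 1 || n_groups > 5) abort("n_groups must be 1-5")
  if (is.null(group_charges)) {
    group_charges <- c(0.4, -0.2, 0.2, -0.1, 0.1)[seq_len(n_groups)]
  } else {
    group_charges <- rep_len(group_charges, n_groups)
  }
  lapply(seq_len(n_groups), function(g) {
    qs <- c(group_charges[g] - 0.1, 0.2, -0.1)   # three atoms per group
    list(
      name = paste0("G", g),
      atoms = tibble(
        atom_name = paste0(c("C", "N", "O"), g),
        dx = c(0, 1.4, 0.7), dy = c(0, 0, 1.2), dz = (g - 1) * 2.6,
        charge = qs,
        lj_epsilon = c(0.08, 0.17, 0.12),
        lj_rmin_half = c(2.0, 1.85, 1.7),
        pb_radius = c(1.9, 1.7, 1.6),
        mass = c(12.011, 14.007, 15.999),
        hbond_role = c("none", "donor_heavy", "acceptor")
      )
    )
  })
}

#' Generate a fully parameterized toy protein-ligand complex
#'
#' The receptor is a chain of `n_residues` four-atom (N, CA, C, O) residues
#' laid out along a gentle arc at ~3.8 A spacing; the ligand sits ~4 A above
#' the chain's midpoint, with one rigid cluster per group tagged G1..Gk.
#' Residue ids start at `first_residue` (default 248, the XIAP-BIR3
#' construct numbering).
#'
#' @param n_residues Number of receptor residues (>= 1).
#' @param ligand_spec List of group definitions, see [default_ligand_spec()].
#' @param seed Integer seed (small coordinate perturbations are seeded).
#' @param first_residue First residue id.
#' @return A parameterized `bir3_topology` with provenance `"synthetic"`.
#' @export
make_toy_complex <- function(n_residues, ligand_spec = default_ligand_spec(),
                             seed = 0, first_residue = 248L) {
  if (n_residues < 1) abort("n_residues must be >= 1")
  if (length(ligand_spec) == 0) abort("ligand_spec must define at least one group")
  .with_seed(seed, {
    # receptor backbone: CHARMM-like partial charges, net 0 per residue
    bb <- tibble(
      atom_name = c("N", "CA", "C", "O"),
      dx = c(0, 1.2, 2.4, 2.9), dy = c(0, 1.0, 0.4, -0.7), dz = c(0, 0, 0.4, 0.6),
      charge = c(-0.30, 0.10, 0.45, -0.25),
      lj_epsilon = c(0.20, 0.07, 0.11, 0.12),
      lj_rmin_half = c(1.85, 2.27, 2.00, 1.70),
      pb_radius = c(1.7, 1.9, 1.9, 1.6),
      mass = c(14.007, 12.011, 12.011, 15.999),
      hbond_role = c("donor_heavy", "none", "none", "acceptor")
    )
    rec <- purrr::map_dfr(seq_len(n_residues), function(i) {
      ang <- 0.12 * (i - 1)
      base <- c(3.8 * (i - 1), 1.5 * sin(ang), 0.8 * cos(ang))
      dplyr::mutate(bb,
                    residue_name = "ALA",
                    residue_id = first_residue + i - 1L,
                    x = base[1] + .data$dx + rnorm(1, 0, 0.02),
                    y = base[2] + .data$dy + rnorm(1, 0, 0.02),
                    z = base[3] + .data$dz + rnorm(1, 0, 0.02))
    })
    mid <- c(3.8 * (n_residues - 1) / 2, 0, 4.2)
    lig <- purrr::imap_dfr(ligand_spec, function(grp, g) {
      a <- as_tibble(grp$atoms)
      dplyr::mutate(a,
                    residue_name = "LIG",
                    residue_id = max(rec$residue_id) + 1L,
                    group_id = grp$name,
                    x = mid[1] + .data$dx, y = mid[2] + .data$dy,
                    z = mid[3] + (if ("dz" %in% names(a)) .data$dz else 0))
    })
    rec$group_id <- NA_character_
    cols <- c("atom_name", "residue_name", "residue_id", "group_id",
              "x", "y", "z", "charge", "lj_epsilon", "lj_rmin_half",
              "pb_radius", "mass", "hbond_role")
    atoms <- dplyr::bind_rows(rec[, cols], lig[, cols])
    atoms$atom_index <- seq_len(nrow(atoms))
    atoms$is_hydrogen <- FALSE
    as_topology(atoms, provenance = "synthetic")
  })
}

#' Recipe for a synthetic conformational ensemble
#'
#' @param topology Base `bir3_topology`.
#' @param sigma Isotropic per-atom coordinate fluctuation, A (>= 0).
#' @param n_frames Number of frames (>= 1).
#' @param hbond_schedules List of schedules, each
#'   `list(donor = <atom_index>, acceptor = <atom_index>, occupancy = f)`
#'   with `0 <= f <= 1`.  The generator plants the donor-acceptor distance
#'   below/above the default H-bond criterion in exactly
#'   `round(f * n_frames)` frames (deterministic frame assignment via a
#'   seeded shuffle, not sampling).
#' @param seed Integer seed.
#' @return An `ensemble_recipe` list.
#' @export
ensemble_recipe <- function(topology, sigma = 0.3, n_frames = 100,
                            hbond_schedules = list(), seed = 0) {
  if (sigma < 0) abort("sigma must be >= 0")
  if (n_frames < 1) abort("n_frames must be >= 1")
  for (s in hbond_schedules) {
    if (!all(c("donor", "acceptor", "occupancy") %in% names(s))) {
      abort("each hbond schedule needs donor, acceptor, occupancy")
    }
    if (s$occupancy < 0 || s$occupancy > 1) abort("occupancy must be in [0, 1]")
    if (!all(c(s$donor, s$acceptor) %in% topology$atom_index)) {
      abort("hbond schedule refers to atoms not in the topology")
    }
  }
  structure(list(topology = topology, sigma = sigma, n_frames = n_frames,
                 hbond_schedules = hbond_schedules, seed = seed),
            class = "ensemble_recipe")
}

#' Generate a fluctuating ensemble with planted hydrogen-bond schedules
#'
#' Frames are the base coordinates plus i.i.d. Gaussian jitter of width
#' `sigma`; for every hydrogen-bond schedule the acceptor atom is then
#' repositioned along the base donor-acceptor direction at 2.9 A (bonded
#' frames) or 6.0 A (unbonded frames) from the donor, so the planted
#' occupancy is exact under the default 3.5 A distance criterion.
#'
#' @param recipe An [ensemble_recipe()].
#' @param frame_interval,temperature Trajectory metadata (ps, K).
#' @return A `bir3_trajectory`.
#' @export
make_ensemble <- function(recipe, frame_interval = 20, temperature = 303.15) {
  stopifnot(inherits(recipe, "ensemble_recipe"))
  top <- recipe$topology
  base <- topology_coords(top)
  n <- nrow(base)
  .with_seed(recipe$seed, {
    bonded <- lapply(recipe$hbond_schedules, function(s) {
      k <- round(s$occupancy * recipe$n_frames)
      sample(recipe$n_frames)[seq_len(k)]
    })
    frames <- lapply(seq_len(recipe$n_frames), function(f) {
      crd <- base
      if (recipe$sigma > 0) {
        crd <- crd + matrix(rnorm(3 * n, 0, recipe$sigma), ncol = 3)
      }
      for (si in seq_along(recipe$hbond_schedules)) {
        s <- recipe$hbond_schedules[[si]]
        di <- match(s$donor, top$atom_index)
        ai <- match(s$acceptor, top$atom_index)
        u <- base[ai, ] - base[di, ]
        nu <- sqrt(sum(u^2))
        u <- if (nu > 1e-9) u / nu else c(1, 0, 0)
        d <- if (f %in% bonded[[si]]) 2.9 else 6.0
        crd[ai, ] <- crd[di, ] + u * d
      }
      dimnames(crd) <- list(NULL, c("x", "y", "z"))
      crd
    })
    new_trajectory(top, frames, frame_interval = frame_interval,
                   temperature = temperature)
  })
}

#' Generate a Gaussian interaction-energy series
#'
#' I.i.d. normal samples standing in for a per-frame receptor-ligand
#' interaction-energy trace, used to exercise the interaction-entropy
#' estimator.
#'
#' @param mean Mean, kcal/mol.
#' @param sigma Fluctuation, kcal/mol (>= 0).
#' @param n Number of samples (>= 1).
#' @param seed Integer seed.
#' @return Numeric vector of length `n`.
#' @export
make_energy_series <- function(mean, sigma, n, seed = 0) {
  if (n < 1) abort("n must be >= 1")
  if (sigma < 0) abort("sigma must be >= 0")
  .with_seed(seed, mean + sigma * rnorm(n))
}

#' Single-atom Born ion system
#'
#' Oracle system for the Poisson-Boltzmann solver: one atom of charge `q`
#' and cavity radius `a` at the origin, whose solvation energy has the
#' closed Born form.
#'
#' @param q Charge, e.
#' @param a Cavity (PB) radius, A (> 0).
#' @return A one-atom `bir3_topology` (segment `"ligand"`).
#' @export
make_born_system <- function(q, a) {
  if (a <= 0) abort("Born radius must be > 0")
  as_topology(tibble(
    atom_index = 1L, atom_name = "ION", residue_name = "ION",
    residue_id = 1L, x = 0, y = 0, z = 0, charge = q,
    lj_epsilon = 0, lj_rmin_half = a, pb_radius = a, mass = 22.99,
    is_hydrogen = FALSE, hbond_role = "none", segment = "ligand",
    group_id = NA_character_
  ), provenance = "synthetic")
}

#' Recipe for a labelled screening library
#'
#' @param model Reference `bir3_pharmacophore` that actives must satisfy.
#' @param n_active,n_inactive Entry counts (defaults 173 and 5417, the
#'   composition of the validation library).
#' @param n_excluded Entries in the 4.5 <= pIC50 <= 6 band, generated only
#'   on request and flagged `"excluded"`.
#' @param jitter_sigma Gaussian jitter applied to active feature points, A;
#'   displacements are clamped to 0.45 x the smallest feature tolerance so
#'   actives match the reference model by construction.  Must be below the
#'   smallest tolerance.
#' @param n_violated Features displaced beyond tolerance per decoy (>= 1,
#'   default 2 so decoys stay unmatched even with one omitted feature).
#' @param corrupt_fraction Fraction of actives corrupted to violate exactly
#'   one feature (they then match only when one omission is allowed).
#' @param seed Integer seed.
#' @return A `library_recipe` list.
#' @export
library_recipe <- function(model, n_active = 173, n_inactive = 5417,
                           n_excluded = 0, jitter_sigma = 0.3,
                           n_violated = 2, corrupt_fraction = 0, seed = 0) {
  stopifnot(inherits(model, "bir3_pharmacophore"))
  if (n_active < 0 || n_inactive < 0 || n_excluded < 0) abort("counts must be >= 0")
  min_tol <- min(model$features$tolerance)
  if (jitter_sigma >= min_tol) {
    abort("jitter_sigma must be below the smallest feature tolerance")
  }
  if (n_violated < 1) abort("decoys must violate at least one feature")
  if (corrupt_fraction < 0 || corrupt_fraction > 1) {
    abort("corrupt_fraction must be in [0, 1]")
  }
  structure(list(model = model, n_active = n_active, n_inactive = n_inactive,
                 n_excluded = n_excluded, jitter_sigma = jitter_sigma,
                 n_violated = n_violated, corrupt_fraction = corrupt_fraction,
                 seed = seed),
            class = "library_recipe")
}

#' @keywords internal
.jitter_clamped <- function(centers, sigma, max_norm) {
  if (nrow(centers) == 0) return(centers)
  d <- matrix(rnorm(length(centers), 0, sigma), ncol = 3)
  nr <- sqrt(rowSums(d^2))
  scale <- ifelse(nr > max_norm, max_norm / nr, 1)
  centers + d * scale
}

#' Generate a labelled screening library
#'
#' Actives carry pIC50 in (6, 9] and reproduce the reference model's feature
#' geometry up to clamped jitter, so they match with zero omissions by
#' construction.  Decoys carry pIC50 in [3, 4.5) and have `n_violated`
#' features displaced to 3.5 x their tolerance.  Heavy atoms are placed at
#' the entry's feature points (used for exclusion-volume tests).
#'
#' @param recipe A [library_recipe()].
#' @return A `bir3_library`: tibble with columns `id`, `label`, `pic50`,
#'   and list-columns `features` (tibble kind/x/y/z per entry) and `atoms`
#'   (heavy-atom coordinate matrix per entry).
#' @export
make_screening_library <- function(recipe) {
  stopifnot(inherits(recipe, "library_recipe"))
  feats <- recipe$model$features
  centers <- as.matrix(feats[, c("x", "y", "z")])
  min_tol <- min(feats$tolerance)
  clamp <- 0.45 * min_tol
  .with_seed(recipe$seed, {
    n_corrupt <- round(recipe$corrupt_fraction * recipe$n_active)
    corrupt_ids <- if (recipe$n_active > 0) {
      sample(recipe$n_active)[seq_len(n_corrupt)]
    } else integer(0)
    mk_entry <- function(id, label, pic50, violate_k) {
      pts <- .jitter_clamped(centers, recipe$jitter_sigma, clamp)
      violated <- integer(0)
      if (violate_k > 0) {
        # place the violated feature radially outside the whole feature
        # cloud, so no kind-respecting assignment can bring it within any
        # tolerance sphere: the planted "no match" is guaranteed by
        # construction, not probabilistically
        centroid <- colMeans(centers)
        d_max <- max(sqrt(rowSums(sweep(centers, 2, centroid)^2)))
        violated <- sample(nrow(feats), violate_k)
        for (v in violated) {
          u <- rnorm(3); u <- u / sqrt(sum(u^2))
          reach <- d_max + (4 + runif(1)) * max(feats$tolerance)
          pts[v, ] <- centroid + u * reach
        }
      }
      tibble(id = id, label = label, pic50 = pic50,
             features = list(tibble(kind = feats$kind,
                                    x = pts[, 1], y = pts[, 2], z = pts[, 3])),
             atoms = list(unname(pts)),
             n_violated = violate_k)
    }
    rows <- list()
    for (i in seq_len(recipe$n_active)) {
      k <- if (i %in% corrupt_ids) 1L else 0L
      rows[[length(rows) + 1]] <-
        mk_entry(sprintf("ACT%05d", i), "active", runif(1, 6 + 1e-6, 9), k)
    }
    for (i in seq_len(recipe$n_inactive)) {
      rows[[length(rows) + 1]] <-
        mk_entry(sprintf("DEC%05d", i), "inactive", runif(1, 3, 4.5 - 1e-6),
                 recipe$n_violated)
    }
    for (i in seq_len(recipe$n_excluded)) {
      rows[[length(rows) + 1]] <-
        mk_entry(sprintf("EXC%05d", i), "excluded", runif(1, 4.5, 6), 0L)
    }
    lib <- dplyr::bind_rows(rows)
    class(lib) <- c("bir3_library", class(lib))
    attr(lib, "reference_model") <- recipe$model$name
    lib
  })
}

#' Write a screening library to a directory
#'
#' Plain-text serialization: `manifest.csv` (id, label, pic50) plus
#' `features.csv` and `atoms.csv` keyed by entry id.
#'
#' @param lib A `bir3_library`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_library <- function(lib, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(tibble(id = lib$id, label = lib$label, pic50 = lib$pic50),
                   file.path(dir, "manifest.csv"))
  featl <- purrr::map2(lib$id, lib$features, ~dplyr::mutate(.y, id = .x))
  readr::write_csv(dplyr::bind_rows(featl), file.path(dir, "features.csv"))
  atoml <- purrr::map2(lib$id, lib$atoms, function(id, m) {
    tibble(id = id, x = m[, 1], y = m[, 2], z = m[, 3])
  })
  readr::write_csv(dplyr::bind_rows(atoml), file.path(dir, "atoms.csv"))
  invisible(dir)
}

#' Read a screening library written by [write_library()]
#' @param dir Library directory.
#' @return A `bir3_library`.
#' @export
read_library <- function(dir) {
  man <- readr::read_csv(file.path(dir, "manifest.csv"), show_col_types = FALSE)
  fe <- readr::read_csv(file.path(dir, "features.csv"), show_col_types = FALSE)
  at <- readr::read_csv(file.path(dir, "atoms.csv"), show_col_types = FALSE)
  lib <- man
  lib$features <- purrr::map(man$id, function(i) {
    f <- fe[fe$id == i, c("kind", "x", "y", "z")]
    as_tibble(f)
  })
  lib$atoms <- purrr::map(man$id, function(i) {
    as.matrix(at[at$id == i, c("x", "y", "z")])
  })
  class(lib) <- c("bir3_library", class(lib))
  lib
}
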