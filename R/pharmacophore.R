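# Simplified structure-based 3D pharmacophores: typed point features
# (hydrogen-bond donor/acceptor, hydrophobic, aromatic-hydrophobic) with
# tolerance spheres, plus exclusion volumes at nearby receptor heavy atoms.
# The perception and matching rules are deliberately simple, documented
# re-implementations of the standard structure-based workflow; proprietary
# perception/alignment internals are out of scope.

.feature_kinds <- c("HBD", "HBA", "H", "HAr")

#' Construct a pharmacophore model
#'
#' @param features Tibble with columns `kind` (HBD/HBA/H/HAr), `x`, `y`,
#'   `z` (A), `tolerance` (A, > 0) and optionally `label`; labels are
#'   auto-assigned per kind (H1, H2, ...) when absent.
#' @param exclusions Optional tibble `x`, `y`, `z`, `radius` (A, > 0).
#' @param name Model name.
#' @param provenance One of `"crystal"`, `"ensemble"`, `"merged"`,
#'   `"edited"`, `"reference"`.
#' @return A `bir3_pharmacophore` object.
#' @export
pharmacophore_model <- function(features, exclusions = NULL,
                                name = "model", provenance = "crystal") {
  features <- as_tibble(features)
  if (nrow(features) == 0) abort("empty model: a pharmacophore needs >= 1 feature")
  if (!all(features$kind %in% .feature_kinds)) {
    abort("feature kind must be one of HBD, HBA, H, HAr")
  }
  if (!"tolerance" %in% names(features)) features$tolerance <- 1.5
  if (any(features$tolerance <= 0)) abort("feature tolerance must be > 0")
  if (!"label" %in% names(features)) {
    features <- features |>
      dplyr::group_by(.data$kind) |>
      dplyr::mutate(label = paste0(dplyr::cur_group()$kind,
                                   dplyr::row_number())) |>
      dplyr::ungroup()
  }
  if (anyDuplicated(features$label) > 0) abort("feature labels must be unique")
  if (is.null(exclusions)) {
    exclusions <- tibble(x = numeric(0), y = numeric(0), z = numeric(0),
                         radius = numeric(0))
  }
  exclusions <- as_tibble(exclusions)
  if (nrow(exclusions) > 0 && any(exclusions$radius <= 0)) {
    abort("exclusion radius must be > 0")
  }
  structure(list(features = features, exclusions = exclusions,
                 name = name, provenance = provenance),
            class = "bir3_pharmacophore")
}

#' @export
print.bir3_pharmacophore <- function(x, ...) {
  counts <- table(factor(x$features$kind, levels = .feature_kinds))
  cat(sprintf("<bir3_pharmacophore> '%s' (%s): %d features (%s), %d exclusion volumes\n",
              x$name, x$provenance, nrow(x$features),
              paste(sprintf("%d %s", counts, names(counts))[counts > 0],
                    collapse = ", "),
              nrow(x$exclusions)))
  invisible(x)
}

#' Perceive ligand feature points from typed atoms
#'
#' Rule-based perception on a typed atom table:
#' \itemize{
#'   \item HBD at every donor heavy atom (`hbond_role == "donor_heavy"`);
#'   \item HBA at every acceptor (`hbond_role == "acceptor"`);
#'   \item H at the centroid of each connected cluster of >= 3 non-ring
#'     carbons (bonded = within `bond_cutoff`, default 1.8 A);
#'   \item HAr at the centroid of each flagged ring (`ring_id` groups).
#' }
#'
#' @param atoms Tibble with `atom_name`, `x`, `y`, `z`, `hbond_role`,
#'   `is_carbon` (logical) and `ring_id` (integer or NA); an error names
#'   any missing typing column.
#' @param bond_cutoff Carbon-carbon connectivity cutoff, A.
#' @return Tibble `kind`, `x`, `y`, `z` of feature points.
#' @export
perceive_features <- function(atoms, bond_cutoff = 1.8) {
  atoms <- as_tibble(atoms)
  need <- c("x", "y", "z", "hbond_role", "is_carbon", "ring_id")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0) {
    abort(paste0("untyped atoms: missing columns ", paste(miss, collapse = ", ")))
  }
  out <- list()
  don <- atoms[atoms$hbond_role == "donor_heavy", ]
  if (nrow(don) > 0) {
    out$hbd <- tibble(kind = "HBD", x = don$x, y = don$y, z = don$z)
  }
  acc <- atoms[atoms$hbond_role == "acceptor", ]
  if (nrow(acc) > 0) {
    out$hba <- tibble(kind = "HBA", x = acc$x, y = acc$y, z = acc$z)
  }
  # aromatic-hydrophobic: one feature per flagged ring
  rings <- atoms[!is.na(atoms$ring_id), ]
  if (nrow(rings) > 0) {
    out$har <- rings |>
      dplyr::group_by(.data$ring_id) |>
      dplyr::summarise(kind = "HAr", x = mean(.data$x), y = mean(.data$y),
                       z = mean(.data$z), .groups = "drop") |>
      dplyr::select("kind", "x", "y", "z")
  }
  # hydrophobic: connected clusters of >= 3 non-ring carbons
  cc <- atoms[atoms$is_carbon & is.na(atoms$ring_id), ]
  if (nrow(cc) >= 3) {
    crd <- cbind(cc$x, cc$y, cc$z)
    d <- .pair_distances(crd, crd)
    adj <- d <= bond_cutoff & d > 0
    comp <- rep(0L, nrow(cc)); cur <- 0L
    for (s in seq_len(nrow(cc))) {
      if (comp[s] != 0L) next
      cur <- cur + 1L
      stack <- s
      while (length(stack) > 0) {
        v <- stack[[1]]; stack <- stack[-1]
        if (comp[v] != 0L) next
        comp[v] <- cur
        stack <- c(stack, which(adj[v, ] & comp == 0L))
      }
    }
    for (g in seq_len(cur)) {
      members <- which(comp == g)
      if (length(members) >= 3) {
        out[[paste0("h", g)]] <- tibble(
          kind = "H", x = mean(cc$x[members]), y = mean(cc$y[members]),
          z = mean(cc$z[members]))
      }
    }
  }
  if (length(out) == 0) return(tibble(kind = character(0), x = numeric(0),
                                      y = numeric(0), z = numeric(0)))
  dplyr::bind_rows(out)
}

#' @keywords internal
.type_ligand_atoms <- function(top) {
  lig <- top[top$segment == "ligand", ]
  if (!"ring_id" %in% names(lig)) lig$ring_id <- NA_integer_
  lig$is_carbon <- if ("is_carbon" %in% names(lig)) lig$is_carbon else
    grepl("^C", lig$atom_name) | abs(lig$mass - 12.011) < 0.5
  lig
}

#' @keywords internal
.feature_retained <- function(kind, center, feat_atom_xyz, prot, hbond_dist,
                              hydrophobic_dist) {
  pxyz <- cbind(prot$x, prot$y, prot$z)
  if (kind == "HBD") {
    partners <- prot$hbond_role == "acceptor"
    if (!any(partners)) return(FALSE)
    d <- sqrt(colSums((t(pxyz[partners, , drop = FALSE]) - feat_atom_xyz)^2))
    any(d <= hbond_dist)
  } else if (kind == "HBA") {
    partners <- prot$hbond_role == "donor_heavy"
    if (!any(partners)) return(FALSE)
    d <- sqrt(colSums((t(pxyz[partners, , drop = FALSE]) - feat_atom_xyz)^2))
    any(d <= hbond_dist)
  } else {
    heavy <- !prot$is_hydrogen
    d <- sqrt(colSums((t(pxyz[heavy, , drop = FALSE]) - center)^2))
    any(d <= hydrophobic_dist)
  }
}

#' Build a structure-based pharmacophore from a complex or ensemble
#'
#' Ligand feature points are perceived with [perceive_features()] and
#' retained only when the complementary receptor condition holds: a
#' receptor acceptor (for HBD) or donor (for HBA) within `hbond_dist`
#' (default 3.5 A) of the feature atom, or any receptor heavy atom within
#' `hydrophobic_dist` (default 4.0 A) of an H/HAr centroid.  For a
#' trajectory the condition must hold in at least `frequency_threshold` of
#' frames (default 0.5) and the feature center is the frame-average
#' position.  Exclusion volumes are placed at receptor heavy atoms within
#' `exclusion_dist` (default 6 A) of any ligand atom.
#'
#' @param x A parameterized `bir3_topology` (single structure) or
#'   `bir3_trajectory`.
#' @param frequency_threshold Retention threshold for ensembles.
#' @param tolerance Feature tolerance radius, A (default 1.5).
#' @param exclusion_radius Exclusion-volume radius, A (default 1.0).
#' @param hbond_dist,hydrophobic_dist,exclusion_dist Geometric rules, A.
#' @param name Model name.
#' @return A `bir3_pharmacophore` (provenance `"crystal"` or `"ensemble"`).
#' @export
build_model <- function(x, frequency_threshold = 0.5, tolerance = 1.5,
                        exclusion_radius = 1.0, hbond_dist = 3.5,
                        hydrophobic_dist = 4.0, exclusion_dist = 6.0,
                        name = NULL) {
  if (inherits(x, "bir3_trajectory")) {
    top <- x$topology
    frames <- x$frames
    prov <- "ensemble"
  } else {
    top <- x
    frames <- list(topology_coords(top))
    prov <- "crystal"
  }
  lig_idx <- which(top$segment == "ligand")
  prot_idx <- which(top$segment == "receptor")
  if (length(lig_idx) == 0 || length(prot_idx) == 0) {
    abort("model building needs both receptor and ligand atoms")
  }
  lig_typed <- .type_ligand_atoms(top)
  # perceive on the first frame to fix the feature set, then track
  # positions/conditions across frames
  per_frame <- lapply(frames, function(f) {
    lt <- lig_typed
    lt$x <- f[lig_idx, 1]; lt$y <- f[lig_idx, 2]; lt$z <- f[lig_idx, 3]
    pt <- top[prot_idx, ]
    pt$x <- f[prot_idx, 1]; pt$y <- f[prot_idx, 2]; pt$z <- f[prot_idx, 3]
    feats <- perceive_features(lt)
    if (nrow(feats) == 0) return(NULL)
    feats$held <- vapply(seq_len(nrow(feats)), function(i) {
      ctr <- c(feats$x[i], feats$y[i], feats$z[i])
      .feature_retained(feats$kind[i], ctr, ctr, pt, hbond_dist,
                        hydrophobic_dist)
    }, logical(1))
    feats
  })
  if (any(vapply(per_frame, is.null, logical(1)))) {
    abort("empty model: no ligand features perceived")
  }
  nfeat <- nrow(per_frame[[1]])
  held_frac <- rowMeans(vapply(per_frame, function(f) f$held, logical(nfeat)))
  avg_xyz <- Reduce(`+`, lapply(per_frame, function(f) cbind(f$x, f$y, f$z))) /
    length(per_frame)
  keep <- held_frac >= frequency_threshold
  if (!any(keep)) abort("empty model: no feature held often enough")
  feats <- tibble(kind = per_frame[[1]]$kind[keep],
                  x = avg_xyz[keep, 1], y = avg_xyz[keep, 2],
                  z = avg_xyz[keep, 3],
                  tolerance = tolerance,
                  frequency = held_frac[keep])
  feats <- feats |>
    dplyr::group_by(.data$kind) |>
    dplyr::mutate(label = paste0(dplyr::cur_group()$kind, dplyr::row_number())) |>
    dplyr::ungroup()
  # exclusion volumes from frame-average coordinates
  avg_all <- Reduce(`+`, frames) / length(frames)
  prot_heavy <- prot_idx[!top$is_hydrogen[prot_idx]]
  d <- .pair_distances(avg_all[prot_heavy, , drop = FALSE],
                       avg_all[lig_idx, , drop = FALSE])
  near <- apply(d, 1, min) <= exclusion_dist
  excl <- tibble(x = avg_all[prot_heavy[near], 1],
                 y = avg_all[prot_heavy[near], 2],
                 z = avg_all[prot_heavy[near], 3],
                 radius = exclusion_radius)
  pharmacophore_model(feats, excl,
                      name = name %||% paste0(prov, "-model"),
                      provenance = prov)
}

#' Merge two pharmacophore models
#'
#' Features of the same kind whose centers lie within `merge_distance`
#' (default 1.5 A) fuse to their midpoint (greedy nearest-pair fusion);
#' all others are carried over.  Exclusion volumes are unioned with the
#' same-rule fusion.  Both models must already be in the same frame of
#' reference.
#'
#' @param a,b `bir3_pharmacophore` models.
#' @param merge_distance Fusion distance, A.
#' @param name Name of the merged model.
#' @return A `bir3_pharmacophore` with provenance `"merged"`.
#' @export
merge_models <- function(a, b, merge_distance = 1.5, name = "merged") {
  fuse <- function(fa, fb, key_cols, dist_cols = c("x", "y", "z")) {
    used_b <- rep(FALSE, nrow(fb))
    rows <- list()
    for (i in seq_len(nrow(fa))) {
      cand <- which(!used_b &
                      (if ("kind" %in% key_cols) fb$kind == fa$kind[i] else TRUE))
      if (length(cand) > 0) {
        d <- sqrt((fb$x[cand] - fa$x[i])^2 + (fb$y[cand] - fa$y[i])^2 +
                    (fb$z[cand] - fa$z[i])^2)
        j <- cand[which.min(d)]
        if (min(d) <= merge_distance) {
          used_b[j] <- TRUE
          row <- fa[i, ]
          row$x <- (fa$x[i] + fb$x[j]) / 2
          row$y <- (fa$y[i] + fb$y[j]) / 2
          row$z <- (fa$z[i] + fb$z[j]) / 2
          rows[[length(rows) + 1]] <- row
          next
        }
      }
      rows[[length(rows) + 1]] <- fa[i, ]
    }
    dplyr::bind_rows(c(rows, list(fb[!used_b, ])))
  }
  fa <- a$features; fb <- b$features
  fa$label <- NULL; fb$label <- NULL
  if (!"frequency" %in% names(fa)) fa$frequency <- NA_real_
  if (!"frequency" %in% names(fb)) fb$frequency <- NA_real_
  feats <- fuse(fa, fb, key_cols = "kind")
  feats <- feats |>
    dplyr::group_by(.data$kind) |>
    dplyr::mutate(label = paste0(dplyr::cur_group()$kind, dplyr::row_number())) |>
    dplyr::ungroup()
  excl <- fuse(a$exclusions, b$exclusions, key_cols = character(0))
  pharmacophore_model(feats, excl, name = name, provenance = "merged")
}

#' Drop features from a model
#'
#' @param model A `bir3_pharmacophore`.
#' @param drop_labels Labels of features to remove (must exist).
#' @return The edited model (provenance `"edited"`).
#' @export
edit_model <- function(model, drop_labels) {
  unknown <- setdiff(drop_labels, model$features$label)
  if (length(unknown) > 0) {
    abort(paste0("unknown feature label(s): ", paste(unknown, collapse = ", ")))
  }
  keep <- !(model$features$label %in% drop_labels)
  if (!any(keep)) abort("empty model: cannot drop all features")
  pharmacophore_model(model$features[keep, ], model$exclusions,
                      name = paste0(model$name, "-edited"),
                      provenance = "edited")
}

#' Serialize a pharmacophore model to structured text
#' @param model A `bir3_pharmacophore`.
#' @param path Output path (YAML).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  yaml::write_yaml(list(
    name = model$name, provenance = model$provenance,
    features = lapply(seq_len(nrow(model$features)), function(i) {
      f <- model$features[i, ]
      list(label = f$label, kind = f$kind,
           center = c(f$x, f$y, f$z), tolerance = f$tolerance)
    }),
    exclusions = lapply(seq_len(nrow(model$exclusions)), function(i) {
      e <- model$exclusions[i, ]
      list(center = c(e$x, e$y, e$z), radius = e$radius)
    })
  ), path)
  invisible(path)
}

#' Read a pharmacophore model written by [write_model()]
#' @param path YAML model file.
#' @return A `bir3_pharmacophore`.
#' @export
read_model <- function(path) {
  y <- yaml::read_yaml(path)
  feats <- dplyr::bind_rows(lapply(y$features, function(f) {
    tibble(kind = f$kind, x = f$center[1], y = f$center[2], z = f$center[3],
           tolerance = f$tolerance, label = f$label)
  }))
  excl <- if (length(y$exclusions) > 0) {
    dplyr::bind_rows(lapply(y$exclusions, function(e) {
      tibble(x = e$center[1], y = e$center[2], z = e$center[3],
             radius = e$radius)
    }))
  } else NULL
  pharmacophore_model(feats, excl, name = y$name, provenance = y$provenance)
}
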