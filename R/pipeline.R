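# End-to-end workflow orchestration: ensemble -> MM-PBSA (+/- entropy) ->
# decomposition -> affinity benchmark, and complex/ensemble ->
# pharmacophore -> screen -> metrics.  One config object drives a run;
# every artifact records the config hash and seed so reruns are
# reproducible.

#' Build a run configuration
#'
#' @param complexes List of per-complex entries, each a list with
#'   `id`, `trajectory` (a `bir3_trajectory`) and optionally `ic50_nM`.
#' @param stride Frame stride for MM-PBSA.
#' @param entropy Character vector of entropy options from
#'   `c("none", "ie")` (normal-mode needs a bonded energy model and is
#'   driven separately via [nm_binding_entropy()]).
#' @param temperature K.
#' @param pb Named list of PB settings (`spacing`, `padding`, `eps_in`,
#'   `eps_out`, `ionic_strength`).
#' @param seed Integer seed recorded in every artifact.
#' @param output_dir Output directory, or `NULL` for no file output.
#' @return A `bir3_config` list.
#' @export
run_config <- function(complexes, stride = 1, entropy = c("none", "ie"),
                       temperature = 303.15,
                       pb = list(spacing = 0.8, padding = 10, eps_in = 1,
                                 eps_out = 80, ionic_strength = 0.15),
                       seed = 1, output_dir = NULL) {
  entropy <- match.arg(entropy, c("none", "ie"), several.ok = TRUE)
  for (cx in complexes) {
    if (!all(c("id", "trajectory") %in% names(cx))) {
      abort("each complex entry needs id and trajectory")
    }
    stopifnot(inherits(cx$trajectory, "bir3_trajectory"))
  }
  cfg <- list(complexes = complexes, stride = stride, entropy = entropy,
              temperature = temperature, pb = pb, seed = seed,
              output_dir = output_dir)
  cfg$hash <- .config_hash(cfg)
  structure(cfg, class = "bir3_config")
}

#' @keywords internal
.config_hash <- function(cfg) {
  desc <- paste(cfg$stride, paste(cfg$entropy, collapse = ","),
                cfg$temperature, paste(unlist(cfg$pb), collapse = ","),
                cfg$seed, length(cfg$complexes),
                paste(vapply(cfg$complexes, `[[`, "", "id"), collapse = ","))
  # small stable polynomial hash (double-precision modular arithmetic);
  # avoids a digest dependency
  bytes <- utf8ToInt(desc)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the MM-PBSA workflow over a set of complexes
#'
#' For every complex and every requested entropy option, computes the
#' per-frame energy series and binding estimate; when at least three
#' complexes carry IC50 values, benchmarks the "none"-entropy predictions
#' against experiment.  All tables carry the config hash and seed.
#'
#' @param config A [run_config()].
#' @return List: `estimates` (tibble: one row per complex x entropy
#'   option), `series` (named list of frame-energy tibbles), `correlation`
#'   (a `bir3_correlation` or `NULL`), `config_hash`, `seed`.  When the
#'   config has an `output_dir`, per-frame and summary CSVs are written
#'   there.
#' @export
run_mmpbsa_workflow <- function(config) {
  stopifnot(inherits(config, "bir3_config"))
  pb <- config$pb
  series_list <- list(); est_rows <- list()
  for (cx in config$complexes) {
    ser <- tryCatch(
      frame_energy_series(cx$trajectory, stride = config$stride,
                          spacing = pb$spacing, padding = pb$padding,
                          eps_in = pb$eps_in, eps_out = pb$eps_out,
                          ionic_strength = pb$ionic_strength),
      error = function(e) {
        abort(sprintf("stage frame_energy_series failed for complex %s: %s",
                      cx$id, conditionMessage(e)))
      })
    series_list[[cx$id]] <- ser
    for (ent in config$entropy) {
      entropy <- if (ent == "ie") {
        interaction_entropy(ser$e_inte, temperature = config$temperature)
      } else NULL
      est <- estimate_binding(ser, entropy)
      est_rows[[length(est_rows) + 1]] <- dplyr::bind_cols(
        tibble(complex_id = cx$id, entropy = ent), glance(est))
    }
  }
  estimates <- dplyr::bind_rows(est_rows)
  correlation <- NULL
  with_ic50 <- purrr::keep(config$complexes, ~!is.null(.x$ic50_nM))
  if (length(with_ic50) >= 3) {
    bench <- tibble(
      complex_id = vapply(with_ic50, `[[`, "", "id"),
      ic50 = vapply(with_ic50, `[[`, 0, "ic50_nM"))
    pred <- estimates[estimates$entropy == config$entropy[1], ]
    bench$dg_pred <- pred$dg[match(bench$complex_id, pred$complex_id)]
    correlation <- benchmark_affinities(bench, pred = "dg_pred",
                                        ic50_unit = "nM",
                                        temperature = config$temperature)
  }
  out <- list(estimates = estimates, series = series_list,
              correlation = correlation, config_hash = config$hash,
              seed = config$seed)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    stamp <- function(df) {
      df$config_hash <- config$hash; df$seed <- config$seed; df
    }
    readr::write_csv(stamp(estimates),
                     file.path(config$output_dir, "binding_estimates.csv"))
    for (id in names(series_list)) {
      readr::write_csv(stamp(series_list[[id]]),
                       file.path(config$output_dir,
                                 paste0("frames_", id, ".csv")))
    }
    if (!is.null(correlation)) {
      readr::write_csv(stamp(glance(correlation)),
                       file.path(config$output_dir, "correlation.csv"))
    }
  }
  out
}

#' Run the pharmacophore workflow
#'
#' Builds a model from a complex and/or ensemble (merging when both are
#' given), optionally applies feature edits, screens the library at 0 and
#' 1 allowed omissions, and emits one metrics row per model/omission --
#' sensitivity, specificity, EF, early AUC (top 1.5% of the ranked
#' library) and full AUC.
#'
#' @param library A `bir3_library`.
#' @param complex Optional parameterized complex `bir3_topology`.
#' @param trajectory Optional `bir3_trajectory`.
#' @param model Optional prebuilt `bir3_pharmacophore` (skips building).
#' @param drop_labels Optional character vector of feature labels to drop
#'   (an edited variant is screened alongside the base model).
#' @param omissions Integer vector from `c(0, 1)`.
#' @param early_fraction Early-AUC fraction (default 0.015).
#' @return List: `models` (named list), `metrics` (tibble, one row per
#'   model x omission), `outcomes` (list of `bir3_screening`).
#' @export
run_pharm_workflow <- function(library, complex = NULL, trajectory = NULL,
                               model = NULL, drop_labels = NULL,
                               omissions = c(0, 1), early_fraction = 0.015) {
  models <- list()
  if (!is.null(model)) {
    models[[model$name]] <- model
  } else {
    mc <- if (!is.null(complex)) build_model(complex, name = "crystal") else NULL
    mt <- if (!is.null(trajectory)) build_model(trajectory, name = "ensemble") else NULL
    if (!is.null(mc) && !is.null(mt)) {
      models[["merged"]] <- merge_models(mc, mt, name = "merged")
    } else if (!is.null(mc)) models[["crystal"]] <- mc
    else if (!is.null(mt)) models[["ensemble"]] <- mt
    else abort("run_pharm_workflow needs a model, a complex, or a trajectory")
  }
  if (!is.null(drop_labels)) {
    base <- models[[length(models)]]
    models[[paste0(base$name, "-edited")]] <- edit_model(base, drop_labels)
  }
  rows <- list(); outcomes <- list()
  for (mn in names(models)) {
    for (om in omissions) {
      oc <- screen_library(models[[mn]], library, max_omitted = om)
      auc_full <- roc_auc(oc$entries$score, oc$entries$label, fraction = 1)
      auc_early <- roc_auc(oc$entries$score, oc$entries$label,
                           fraction = early_fraction)
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble(model = mn, omitted = om),
        screening_metrics(oc),
        tibble(auc_early = auc_early, auc_full = auc_full))
      outcomes[[paste(mn, om, sep = "_omit")]] <- oc
    }
  }
  list(models = models, metrics = dplyr::bind_rows(rows), outcomes = outcomes)
}
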