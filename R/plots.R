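# ggplot2 visualisations for the main result types.

#' Plot a per-frame energy series
#'
#' @param series Tibble from [frame_energy_series()].
#' @return A ggplot: per-frame components and total.
#' @export
plot_energy_series <- function(series) {
  long <- tidyr::pivot_longer(
    series, c("elec", "vdw", "g_polar", "g_nonpolar", "total"),
    names_to = "component", values_to = "energy")
  ggplot(long, aes(x = .data$frame, y = .data$energy,
                   colour = .data$component)) +
    geom_line() +
    labs(x = "frame", y = "energy (kcal/mol)",
         title = "MM-PBSA per-frame energy components") +
    theme_minimal()
}

#' @export
autoplot.bir3_decomposition <- function(object, ...) {
  key <- if ("residue_id" %in% names(object)) "residue_id" else "group_id"
  value_cols <- intersect(c("polar", "nonpolar"), names(object))
  if (length(value_cols) == 0) value_cols <- "e_inte"
  long <- tidyr::pivot_longer(object, dplyr::all_of(value_cols),
                              names_to = "part", values_to = "energy")
  ggplot(long, aes(x = factor(.data[[key]]), y = .data$energy,
                   fill = .data$part)) +
    geom_col(position = "stack") +
    labs(x = key, y = "contribution (kcal/mol)",
         title = "Binding free-energy decomposition") +
    theme_minimal()
}

#' @export
autoplot.bir3_contact_map <- function(object, ...) {
  ggplot(object, aes(x = factor(.data$ligand_atom),
                     y = factor(.data$residue_id),
                     fill = .data$frequency)) +
    geom_tile() +
    scale_fill_gradient2(low = "white", high = "firebrick",
                         limits = c(0, 1)) +
    labs(x = "ligand atom", y = "residue",
         fill = "contact\nfrequency",
         title = "Residue-ligand contact map") +
    theme_minimal()
}

#' @export
autoplot.bir3_correlation <- function(object, ...) {
  tab <- object$table
  use <- if ("exclude" %in% names(tab)) !tab$exclude else TRUE
  pred_col <- setdiff(names(tab), c("complex_id", "ic50", "ic50_nM",
                                    "dg_exp", "dg_exp_printed", "exclude"))[1]
  ggplot(tab[use, ], aes(x = .data$dg_exp, y = .data[[pred_col]])) +
    geom_point(size = 3) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    labs(x = "experimental dG (kcal/mol)", y = "predicted dG (kcal/mol)",
         title = sprintf("Prediction vs experiment (r = %.3f)",
                         object$pearson_r)) +
    theme_minimal()
}

#' ROC curve for a screening run
#'
#' @param outcome A `bir3_screening` with per-entry scores.
#' @return A ggplot of the ROC curve with the AUC in the title.
#' @export
plot_roc <- function(outcome) {
  stopifnot(inherits(outcome, "bir3_screening"))
  if (is.null(outcome$entries)) abort("outcome carries no per-entry scores")
  e <- outcome$entries
  auc <- roc_auc(e$score, e$label)
  s <- e$score
  s[is.na(s)] <- min(s, na.rm = TRUE) - 1
  ord <- order(s, decreasing = TRUE)
  lab <- e$label[ord] == "active"
  df <- tibble(fpr = c(0, cumsum(!lab) / sum(!lab)),
               tpr = c(0, cumsum(lab) / sum(lab)))
  ggplot(df, aes(x = .data$fpr, y = .data$tpr)) +
    geom_line(colour = "steelblue") +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    labs(x = "false-positive rate", y = "true-positive rate",
         title = sprintf("ROC (AUC = %.2f)", auc)) +
    theme_minimal()
}
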