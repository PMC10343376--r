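# Experimental-affinity benchmarking: IC50 -> dG_exp conversion and
# correlation / rank-concordance of predicted binding free energies.

#' Experimental binding free energy from IC50
#'
#' \eqn{\Delta G_{exp} = RT \ln(IC_{50})} with IC50 dimensionless in molar
#' units, R = 1.9858775e-3 kcal/K/mol.  Negative for sub-molar IC50.
#'
#' @param ic50 IC50 value(s); interpreted according to `unit`.
#' @param temperature K, default 303.15.
#' @param unit One of `"M"`, `"mM"`, `"uM"`, `"nM"` (explicit units are
#'   required because silent molar assumptions are the classic failure
#'   mode here).
#' @return Free energy, kcal/mol (vectorized).
#' @export
delta_g_exp <- function(ic50, temperature = 303.15,
                        unit = c("M", "mM", "uM", "nM")) {
  unit <- match.arg(unit)
  scale <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9)[[unit]]
  m <- ic50 * scale
  if (any(m <= 0)) abort("IC50 must be > 0")
  .const$R_gas * temperature * log(m)
}

#' Pearson correlation between two affinity vectors
#'
#' Thin validated wrapper around the sample Pearson correlation.
#'
#' @param x,y Numeric vectors, equal length >= 3, nonzero variance.
#' @return Correlation coefficient in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("length mismatch")
  if (length(x) < 3) abort("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) abort("zero variance input")
  stats::cor(x, y, method = "pearson")
}

#' Rank concordance of predicted vs experimental affinities
#'
#' A prediction ranks ligands "in the correct order" when the orderings
#' agree exactly: zero discordant pairs in the Kendall sense.  Tied pairs
#' in either list are reported and treated as concordance-neutral.
#'
#' @param dg_exp,dg_pred Numeric vectors (equal length >= 3).
#' @return List: `concordant` (TRUE iff no discordant pairs),
#'   `n_discordant`, `n_tied`, `n_pairs`.
#' @export
rank_concordance <- function(dg_exp, dg_pred) {
  if (length(dg_exp) != length(dg_pred)) abort("length mismatch")
  if (length(dg_exp) < 3) abort("need at least 3 pairs")
  n <- length(dg_exp)
  disc <- 0L; tied <- 0L
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      a <- sign(dg_exp[j] - dg_exp[i]); b <- sign(dg_pred[j] - dg_pred[i])
      if (a == 0 || b == 0) tied <- tied + 1L
      else if (a != b) disc <- disc + 1L
    }
  }
  if (tied > 0) inform(sprintf("rank_concordance: %d tied pair(s), treated as neutral", tied))
  list(concordant = disc == 0L, n_discordant = disc, n_tied = tied,
       n_pairs = n * (n - 1L) %/% 2L)
}

#' Benchmark predicted binding free energies against experiment
#'
#' Converts IC50 values to \eqn{\Delta G_{exp}} and reports the Pearson
#' correlation and rank concordance with the predictions.  Rows whose
#' printed reference \eqn{\Delta G_{exp}} (if supplied) disagrees with the
#' computed one by more than `flag_tol` are flagged rather than reconciled.
#'
#' @param data Data frame with columns `complex_id`, `ic50` and a
#'   prediction column named by `pred`; optional `dg_exp_printed` and
#'   `exclude` (logical; excluded rows -- e.g. a peptide reference ligand
#'   among synthetic ones -- are dropped from the statistics but echoed).
#' @param pred Name of the prediction column.
#' @param ic50_unit Unit of the `ic50` column (default `"nM"`).
#' @param temperature K.
#' @param flag_tol Discrepancy flag threshold, kcal/mol (default 0.02).
#' @return A `bir3_correlation` list: `table` (echoed tibble with computed
#'   `dg_exp`), `n`, `pearson_r`, `concordant`, `n_discordant`, `flags`.
#' @export
benchmark_affinities <- function(data, pred = "dg_pred", ic50_unit = "nM",
                                 temperature = 303.15, flag_tol = 0.02) {
  data <- as_tibble(data)
  if (!pred %in% names(data)) abort(paste0("missing prediction column ", pred))
  data$dg_exp <- delta_g_exp(data$ic50, temperature, unit = ic50_unit)
  flags <- character(0)
  if ("dg_exp_printed" %in% names(data)) {
    off <- which(abs(data$dg_exp - data$dg_exp_printed) > flag_tol)
    flags <- sprintf(
      "%s: computed dG_exp %.2f differs from tabulated %.2f kcal/mol",
      data$complex_id[off], data$dg_exp[off], data$dg_exp_printed[off])
    for (f in flags) warn(f)
  }
  use <- if ("exclude" %in% names(data)) !data$exclude else rep(TRUE, nrow(data))
  x <- data$dg_exp[use]; y <- data[[pred]][use]
  rc <- rank_concordance(x, y)
  structure(list(table = data, n = sum(use), pearson_r = pearson_r(x, y),
                 concordant = rc$concordant, n_discordant = rc$n_discordant,
                 flags = flags),
            class = "bir3_correlation")
}

#' @export
print.bir3_correlation <- function(x, ...) {
  cat(sprintf("<bir3_correlation> n = %d, Pearson r = %.5f, rank-concordant: %s\n",
              x$n, x$pearson_r, x$concordant))
  if (length(x$flags)) cat(" flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
glance.bir3_correlation <- function(x, ...) {
  tibble(n = x$n, pearson_r = x$pearson_r, concordant = x$concordant,
         n_discordant = x$n_discordant, n_flags = length(x$flags))
}

#' Experimental affinities and MM-PBSA predictions for XIAP-BIR3 complexes
#'
#' The reference benchmark table bundled with the package: the four
#' crystallographic XIAP-BIR3 complexes with synthetic ligands (PDB ids
#' 5C7C, 5M6M, 5OQW, 5M6L) plus the docked AVPI tetrapeptide reference,
#' their fluorescence-polarization IC50 values (nM), the tabulated
#' \eqn{\Delta G_{exp}} values, and published MM-PBSA predictions from
#' 50-ns HMR-parametrized trajectories without entropic term
#' (`dg_pred_hmr`) and with the interaction-entropy term
#' (`dg_pred_hmr_ie`).  The AVPI row is marked `exclude = TRUE`: it is a
#' peptide, not a synthetic ligand, and its tabulated \eqn{\Delta G_{exp}}
#' (-8.91) disagrees with the IC50 conversion (-9.00), which
#' [benchmark_affinities()] flags.
#'
#' @return Tibble with columns `complex_id`, `ic50_nM`, `dg_exp_printed`,
#'   `dg_pred_hmr`, `dg_pred_hmr_ie`, `exclude`.
#' @export
xiap_affinity_table <- function() {
  path <- system.file("extdata", "xiap_affinities.csv", package = "xbir3")
  readr::read_csv(path, show_col_types = FALSE)
}

#' Published screening counts for the five pharmacophore variants
#'
#' TP/TN counts from screening the 173-active / 5417-inactive validation
#' library against pharmacophore variants 1-5 at zero or one omitted
#' feature, as tabulated in the reference screen.  Use with
#' [screening_outcome()] and [screening_metrics()] to recompute
#' sensitivity, specificity and enrichment factors from the raw counts.
#'
#' @return Tibble `pharmacophore`, `omitted`, `tp`, `tn`.
#' @export
xiap_screening_counts <- function() {
  path <- system.file("extdata", "screening_counts.csv", package = "xbir3")
  readr::read_csv(path, show_col_types = FALSE)
}
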