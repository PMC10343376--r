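# Virtual screening against a pharmacophore model: deterministic
# exhaustive feature matching with optional single-feature omission, and
# the evaluation statistics (sensitivity, specificity, enrichment factor,
# full and early ROC AUC).

#' @keywords internal
.injections <- function(n_slots, pool) {
  # all ordered selections of length n_slots from pool (list of int vectors)
  if (n_slots == 0) return(list(integer(0)))
  out <- list()
  rec <- function(chosen, remaining) {
    if (length(chosen) == n_slots) {
      out[[length(out) + 1]] <<- chosen
      return(invisible(NULL))
    }
    for (p in remaining) rec(c(chosen, p), setdiff(remaining, p))
  }
  rec(integer(0), pool)
  out
}

#' @keywords internal
.count_assignments <- function(model_feats, entry_feats) {
  total <- 1
  for (k in unique(model_feats$kind)) {
    m <- sum(model_feats$kind == k)
    e <- sum(entry_feats$kind == k)
    if (e < m) return(0)
    total <- total * prod(seq(e, e - m + 1))
  }
  total
}

#' Match a library entry against a pharmacophore model
#'
#' Deterministic exhaustive matching: for each allowed omission set (none,
#' or each single model feature when `max_omitted = 1`), every
#' kind-respecting injective assignment of model features to entry feature
#' points is enumerated; the entry is rigidly superposed onto the model
#' over the assigned pairs (Kabsch on feature centers) and accepted iff
#' every assigned pair lies within its feature tolerance after
#' superposition and no entry heavy atom falls inside an exclusion volume.
#' Among acceptances the lowest-RMSD one is reported; ties break to fewer
#' omissions, then lexicographic omitted label.  Assignments whose internal
#' feature-distance pattern cannot fit within tolerances are pruned before
#' superposition.  With fewer than 3 assigned pairs the entry is compared
#' in place (no superposition), since a rigid fit is underdetermined.
#'
#' @param model A `bir3_pharmacophore`.
#' @param entry_features Tibble `kind`, `x`, `y`, `z` of the entry's
#'   feature points.
#' @param entry_atoms Optional heavy-atom coordinate matrix for
#'   exclusion-volume tests.
#' @param max_omitted 0 or 1 omitted model features.
#' @param max_assignments Combinatorial guard (default 1e6): more enumerated
#'   assignments than this raises an error suggesting fewer same-kind
#'   features.
#' @return List: `matched` (logical), `omitted` (label or NA), `rmsd`
#'   (feature-fit RMSD, NA when unmatched).
#' @export
match_entry <- function(model, entry_features, entry_atoms = NULL,
                        max_omitted = 0, max_assignments = 1e6) {
  stopifnot(max_omitted %in% c(0, 1))
  entry_features <- as_tibble(entry_features)
  mf <- model$features
  omission_sets <- list(character(0))
  if (max_omitted == 1 && nrow(mf) > 1) {
    omission_sets <- c(omission_sets,
                       as.list(sort(mf$label)))
  }
  excl <- model$exclusions
  best <- list(matched = FALSE, omitted = NA_character_, rmsd = NA_real_,
               n_omitted = Inf)
  for (om in omission_sets) {
    feats <- mf[!(mf$label %in% om), , drop = FALSE]
    n_assign <- .count_assignments(feats, entry_features)
    if (n_assign > max_assignments) {
      abort(paste0("assignment enumeration too large (", format(n_assign),
                   "); reduce the number of same-kind features"))
    }
    if (n_assign == 0) next
    # per-kind injections composed into full assignments
    kinds <- unique(feats$kind)
    per_kind <- lapply(kinds, function(k) {
      slots <- which(feats$kind == k)
      pool <- which(entry_features$kind == k)
      lapply(.injections(length(slots), pool), function(sel) {
        cbind(slot = slots, pt = sel)
      })
    })
    grid <- expand.grid(lapply(per_kind, seq_along))
    mcent <- as.matrix(feats[, c("x", "y", "z")])
    ecent <- as.matrix(entry_features[, c("x", "y", "z")])
    tol <- feats$tolerance
    mdist <- .pair_distances(mcent, mcent)
    for (g in seq_len(nrow(grid))) {
      asn <- do.call(rbind, lapply(seq_along(per_kind), function(ki) {
        per_kind[[ki]][[grid[g, ki]]]
      }))
      asn <- asn[order(asn[, "slot"]), , drop = FALSE]
      epts <- ecent[asn[, "pt"], , drop = FALSE]
      # prune: internal distances must be compatible within pair tolerances
      edist <- .pair_distances(epts, epts)
      tolpair <- outer(tol, tol, "+")
      if (any(abs(edist - mdist) > tolpair)) next
      if (nrow(epts) >= 3) {
        sup <- tryCatch(kabsch_superpose(mcent, epts),
                        error = function(e) NULL)
        if (is.null(sup)) next
        fitted <- apply_superposition(sup, epts)
        moved_atoms <- if (!is.null(entry_atoms)) {
          apply_superposition(sup, entry_atoms)
        } else NULL
        rmsd <- sup$rmsd
      } else {
        fitted <- epts
        moved_atoms <- entry_atoms
        rmsd <- sqrt(mean(rowSums((fitted - mcent)^2)))
      }
      resid <- sqrt(rowSums((fitted - mcent)^2))
      if (any(resid > tol)) next
      if (!is.null(moved_atoms) && nrow(excl) > 0) {
        dex <- .pair_distances(as.matrix(moved_atoms),
                               as.matrix(excl[, c("x", "y", "z")]))
        inside <- sweep(dex, 2, excl$radius, "<")
        if (any(inside)) next
      }
      cand <- list(matched = TRUE,
                   omitted = if (length(om) > 0) om else NA_character_,
                   rmsd = rmsd, n_omitted = length(om))
      better <- !best$matched ||
        (cand$rmsd < best$rmsd - 1e-12) ||
        (abs(cand$rmsd - best$rmsd) <= 1e-12 &&
           (cand$n_omitted < best$n_omitted ||
              (cand$n_omitted == best$n_omitted &&
                 !is.na(cand$omitted) && !is.na(best$omitted) &&
                 cand$omitted < best$omitted)))
      if (better) best <- cand
    }
  }
  best$n_omitted <- NULL
  best
}

#' Screen a labelled library against a pharmacophore model
#'
#' Runs [match_entry()] on every entry (entries labelled `"excluded"` --
#' the 4.5 <= pIC50 <= 6 band -- are skipped), tallies the confusion
#' counts, and attaches per-entry scores for ROC analysis (score =
#' -alignment RMSD for matches; non-matches rank below every match).
#'
#' @param model A `bir3_pharmacophore`.
#' @param library A `bir3_library` (see [make_screening_library()] /
#'   [read_library()]).
#' @param max_omitted 0 or 1 omitted features during alignment.
#' @return A `bir3_screening` object with fields `tp`, `fp`, `tn`, `fn`,
#'   `A`, `I`, `D`, `htot`, `max_omitted`, and `entries` (tibble `id`,
#'   `label`, `matched`, `omitted`, `rmsd`, `score`).
#' @export
screen_library <- function(model, library, max_omitted = 0) {
  use <- library$label != "excluded"
  if (!any(use)) abort("library has no non-excluded entries")
  lib <- library[use, ]
  res <- purrr::pmap(list(lib$features, lib$atoms), function(fe, at) {
    match_entry(model, fe, at, max_omitted = max_omitted)
  })
  entries <- tibble(
    id = lib$id, label = lib$label,
    matched = purrr::map_lgl(res, "matched"),
    omitted = purrr::map_chr(res, function(r) r$omitted %||% NA_character_),
    rmsd = purrr::map_dbl(res, "rmsd")
  )
  entries$score <- ifelse(entries$matched, -entries$rmsd, NA_real_)
  tp <- sum(entries$matched & entries$label == "active")
  fp <- sum(entries$matched & entries$label == "inactive")
  fn <- sum(!entries$matched & entries$label == "active")
  tn <- sum(!entries$matched & entries$label == "inactive")
  screening_outcome(tp = tp, tn = tn, A = tp + fn, I = tn + fp,
                    max_omitted = max_omitted, entries = entries,
                    model_name = model$name)
}

#' Construct a screening outcome from confusion counts
#'
#' Useful both as the container behind [screen_library()] and for
#' "count replay": recomputing the published evaluation metrics from
#' tabulated TP/TN counts without re-running a screen.
#'
#' @param tp,tn True-positive and true-negative counts.
#' @param A,I Numbers of active and inactive entries in the dataset.
#' @param max_omitted Omission setting the counts refer to.
#' @param entries Optional per-entry tibble (from a real screen).
#' @param model_name Optional model name.
#' @return A `bir3_screening` object.
#' @export
screening_outcome <- function(tp, tn, A, I, max_omitted = 0,
                              entries = NULL, model_name = NULL) {
  if (tp > A || tn > I || tp < 0 || tn < 0) abort("counts inconsistent with A/I")
  structure(list(tp = tp, fp = I - tn, tn = tn, fn = A - tp,
                 A = A, I = I, D = A + I, htot = tp + (I - tn),
                 max_omitted = max_omitted, entries = entries,
                 model_name = model_name),
            class = "bir3_screening")
}

#' @export
print.bir3_screening <- function(x, ...) {
  m <- screening_metrics(x)
  cat(sprintf(
    "<bir3_screening> TP %d / FP %d / TN %d / FN %d (A=%d, I=%d, omit %d)\n",
    x$tp, x$fp, x$tn, x$fn, x$A, x$I, x$max_omitted))
  cat(sprintf("  sensitivity %.1f%%, specificity %.1f%%, EF %s\n",
              m$sensitivity, m$specificity,
              ifelse(is.na(m$ef), "undefined (no hits)", sprintf("%.1f", m$ef))))
  invisible(x)
}

#' Screening evaluation metrics
#'
#' Sensitivity = TP/A, specificity = TN/I (both reported as percentages),
#' enrichment factor EF = (TP/Htot) / (A/D) with Htot = TP + FP and D the
#' full labelled dataset size A + I.  EF is undefined (NA) when the hit
#' list is empty.
#'
#' @param outcome A `bir3_screening`.
#' @return One-row tibble `sensitivity` (%), `specificity` (%), `ef`,
#'   `tp`, `fp`, `tn`, `fn`, `htot`.
#' @export
screening_metrics <- function(outcome) {
  stopifnot(inherits(outcome, "bir3_screening"))
  if (outcome$A == 0 || outcome$I == 0) {
    abort("screening metrics need both actives and inactives in the dataset")
  }
  ef <- if (outcome$htot == 0) NA_real_ else {
    (outcome$tp / outcome$htot) / (outcome$A / outcome$D)
  }
  tibble(sensitivity = 100 * outcome$tp / outcome$A,
         specificity = 100 * outcome$tn / outcome$I,
         ef = ef, tp = outcome$tp, fp = outcome$fp, tn = outcome$tn,
         fn = outcome$fn, htot = outcome$htot)
}

#' @export
glance.bir3_screening <- function(x, ...) {
  m <- screening_metrics(x)
  dplyr::bind_cols(tibble(model = x$model_name %||% NA_character_,
                          max_omitted = x$max_omitted), m)
}

#' ROC area under the curve (full or early)
#'
#' Full AUC by the Mann-Whitney pair-counting equivalence (probability
#' that a random active scores above a random inactive; ties count 1/2).
#' With `fraction < 1` the normalized early AUC is returned: the ROC curve
#' is traced over the top `fraction` of the ranked library only and the
#' partial area over the covered false-positive range is standardized
#' (McClish) so that random ranking scores 0.5 and perfect early
#' retrieval scores 1.  Entries with `NA` scores (non-matches) rank below
#' all scored entries, tied among themselves.
#'
#' @param scores Numeric scores, higher = more active-like; NA allowed.
#' @param labels Logical or character; `TRUE`/`"active"` marks actives.
#' @param fraction Fraction of the ranked library to evaluate, (0, 1].
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels, fraction = 1.0) {
  if (is.character(labels)) labels <- labels == "active"
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) abort("length mismatch")
  if (!any(labels) || all(labels)) abort("both classes must be present")
  if (fraction <= 0 || fraction > 1) abort("fraction must be in (0, 1]")
  s <- scores
  floor_score <- if (all(is.na(s))) 0 else min(s, na.rm = TRUE) - 1
  s[is.na(s)] <- floor_score
  if (fraction >= 1) {
    r <- rank(s, ties.method = "average")
    n1 <- sum(labels); n0 <- sum(!labels)
    return((sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0))
  }
  # early AUC over the top fraction of the ranked list
  n <- length(s)
  m <- max(1L, ceiling(fraction * n))
  ord <- order(s, decreasing = TRUE)
  top <- ord[seq_len(m)]
  n1 <- sum(labels); n0 <- sum(!labels)
  # walk thresholds down the top list, accumulating trapezoids in
  # (FPR, TPR); group tied scores into single steps
  sv <- s[top]; lv <- labels[top]
  steps <- split(seq_len(m), factor(-sv, levels = unique(-sv)))
  tpr <- 0; fpr <- 0; area <- 0
  for (st in steps) {
    dt <- sum(lv[st]) / n1
    df <- sum(!lv[st]) / n0
    area <- area + df * (tpr + dt / 2)
    tpr <- tpr + dt; fpr <- fpr + df
  }
  if (fpr == 0) {
    # no inactive reached the early list: perfect early retrieval if any
    # active did, else undefined -> 0
    return(if (tpr > 0) 1 else 0)
  }
  # McClish standardization over the covered FPR range [0, fpr]:
  # random (TPR = FPR) has area fpr^2/2, the best achievable is fpr
  a_rand <- fpr^2 / 2
  0.5 * (1 + (area - a_rand) / (fpr - a_rand))
}
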