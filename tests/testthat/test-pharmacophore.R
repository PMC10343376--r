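test_that("feature perception applies the four rules", {
  # hydroxyl-like fragment: O that is both donor and acceptor
  oh <- tibble::tibble(
    atom_name = "O1", x = 1, y = 2, z = 3,
    hbond_role = "donor_heavy", is_carbon = FALSE, ring_id = NA_integer_)
  f1 <- perceive_features(oh)
  expect_equal(f1$kind, "HBD")
  oh2 <- dplyr::bind_rows(oh, dplyr::mutate(oh, hbond_role = "acceptor"))
  f2 <- perceive_features(oh2)
  expect_setequal(f2$kind, c("HBD", "HBA"))
  expect_equal(f2$x, c(1, 1))
  # 6-carbon flagged ring -> one HAr at the centroid
  th <- seq(0, 2 * pi, length.out = 7)[1:6]
  ring <- tibble::tibble(
    atom_name = paste0("C", 1:6), x = 1.4 * cos(th), y = 1.4 * sin(th),
    z = 0, hbond_role = "none", is_carbon = TRUE, ring_id = 1L)
  fr <- perceive_features(ring)
  expect_equal(fr$kind, "HAr")
  expect_equal(c(fr$x, fr$y, fr$z), c(0, 0, 0), tolerance = 1e-9)
  # isolated 4-carbon chain -> one H at the centroid
  chain <- tibble::tibble(
    atom_name = paste0("C", 1:4), x = c(0, 1.5, 3.0, 4.5), y = 0, z = 0,
    hbond_role = "none", is_carbon = TRUE, ring_id = NA_integer_)
  fc <- perceive_features(chain)
  expect_equal(fc$kind, "H")
  expect_equal(fc$x, 2.25)
  # two carbons only: no hydrophobic cluster
  expect_equal(nrow(perceive_features(chain[1:2, ])), 0)
  expect_error(perceive_features(chain[, 1:3]), "missing columns")
})

test_that("model building keeps only features with a receptor partner", {
  top <- planted_complex()
  m <- build_model(top)
  expect_setequal(m$features$kind, c("HBD", "HBA", "H"))
  expect_equal(nrow(m$features), 3)
  expect_gt(nrow(m$exclusions), 0)
  # all exclusion volumes sit on receptor heavy atoms within 6 A
  rec <- top[top$segment == "receptor", ]
  d <- sqrt(outer(m$exclusions$x, rec$x, "-")^2 +
              outer(m$exclusions$y, rec$y, "-")^2 +
              outer(m$exclusions$z, rec$z, "-")^2)
  expect_true(all(apply(d, 1, min) < 1e-9))
})

test_that("frozen-ensemble models equal the single-frame model", {
  top <- planted_complex()
  single <- build_model(top)
  frozen <- new_trajectory(top, replicate(4, topology_coords(top),
                                          simplify = FALSE))
  ens <- build_model(frozen)
  expect_equal(ens$features$kind, single$features$kind)
  expect_equal(ens$features$x, single$features$x, tolerance = 1e-12)
  expect_equal(nrow(ens$exclusions), nrow(single$exclusions))
})

test_that("ensemble retention follows the frequency threshold", {
  top <- planted_complex()
  base <- topology_coords(top)
  # break the ligand-donor H-bond (atom NL, row 6) in 60% of frames
  broken <- base; broken[6, 2] <- broken[6, 2] - 5
  frames <- c(replicate(4, base, simplify = FALSE),
              replicate(6, broken, simplify = FALSE))
  traj <- new_trajectory(top, frames)
  m50 <- build_model(traj, frequency_threshold = 0.5)
  expect_false("HBD" %in% m50$features$kind)   # held in 40% < 50%
  m30 <- build_model(traj, frequency_threshold = 0.3)
  expect_true("HBD" %in% m30$features$kind)
})

test_that("merging is idempotent, unions distant features and fuses close ones", {
  m <- ref_model8()
  self <- merge_models(m, m)
  expect_equal(nrow(self$features), nrow(m$features))
  expect_equal(sort(self$features$x), sort(m$features$x), tolerance = 1e-12)
  # disjoint models: union
  shifted <- ref_model8()
  shifted$features$x <- shifted$features$x + 50
  both <- merge_models(m, shifted)
  expect_equal(nrow(both$features), 16)
  # 5-feature and 6-feature models sharing 3 fusable features -> 8
  a <- pharmacophore_model(m$features[1:5, ])
  b6 <- m$features[c(1:3, 6:8), ]
  b6$x[1:3] <- b6$x[1:3] + 0.4      # within merge distance of a's first three
  b <- pharmacophore_model(b6)
  merged <- merge_models(a, b)
  expect_equal(nrow(merged$features), 8)
  fused <- merged$features[1, ]
  expect_equal(fused$x, m$features$x[1] + 0.2, tolerance = 1e-9)
})

test_that("editing drops named features and refuses unknown or all labels", {
  m <- ref_model8()
  e <- edit_model(m, "H4")
  expect_equal(nrow(e$features), 7)
  expect_false("H4" %in% e$features$label)
  expect_equal(e$provenance, "edited")
  expect_equal(nrow(edit_model(m, character(0))$features), 8)
  expect_error(edit_model(m, "Z9"), "unknown feature")
  expect_error(edit_model(m, m$features$label), "cannot drop all")
})

test_that("models survive a serialization round trip", {
  m <- ref_model8()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model(m, path)
  back <- read_model(path)
  expect_equal(back$features$kind, m$features$kind)
  expect_equal(back$features$x, m$features$x)
  expect_equal(back$exclusions$radius, m$exclusions$radius)
})

test_that("entries at the model geometry match; displaced features need omission", {
  m <- ref_model8()
  exact <- m$features[, c("kind", "x", "y", "z")]
  res <- match_entry(m, exact, max_omitted = 0)
  expect_true(res$matched)
  expect_lt(res$rmsd, 1e-9)
  expect_true(is.na(res$omitted))
  # one feature displaced by 2x tolerance
  off <- exact
  off$x[4] <- off$x[4] + 2 * m$features$tolerance[4] + 0.5
  expect_false(match_entry(m, off, max_omitted = 0)$matched)
  res1 <- match_entry(m, off, max_omitted = 1)
  expect_true(res1$matched)
  expect_equal(res1$omitted, m$features$label[4])
})

test_that("exclusion volumes veto matches regardless of omissions", {
  m <- ref_model8()
  exact <- m$features[, c("kind", "x", "y", "z")]
  atoms_ok <- as.matrix(exact[, c("x", "y", "z")])
  expect_true(match_entry(m, exact, atoms_ok, max_omitted = 0)$matched)
  atoms_bad <- rbind(atoms_ok, c(8, 8, 8))   # inside the exclusion sphere
  expect_false(match_entry(m, exact, atoms_bad, max_omitted = 0)$matched)
  expect_false(match_entry(m, exact, atoms_bad, max_omitted = 1)$matched)
})

test_that("matching is invariant under rigid motion of the entry", {
  m <- ref_model8()
  exact <- m$features[, c("kind", "x", "y", "z")]
  atoms <- as.matrix(exact[, c("x", "y", "z")])
  for (seed in 1:3) {
    mo <- random_rigid_motion(seed)
    pts <- apply_rigid(as.matrix(exact[, c("x", "y", "z")]), mo)
    moved <- exact
    moved$x <- pts[, 1]; moved$y <- pts[, 2]; moved$z <- pts[, 3]
    res <- match_entry(m, moved, apply_rigid(atoms, mo), max_omitted = 0)
    expect_true(res$matched)
    expect_lt(res$rmsd, 1e-6)
  }
})

test_that("planted libraries screen to their constructed confusion counts", {
  m <- ref_model8()
  lib <- make_screening_library(
    library_recipe(m, n_active = 20, n_inactive = 60, seed = 4))
  oc <- screen_library(m, lib, max_omitted = 0)
  expect_equal(oc$tp, 20)
  expect_equal(oc$fp, 0)
  met <- screening_metrics(oc)
  expect_equal(met$sensitivity, 100)
  expect_equal(met$specificity, 100)
  expect_equal(met$ef, oc$D / oc$A, tolerance = 1e-12)
})

test_that("corrupted actives lower omission-0 sensitivity but not omission-1", {
  m <- ref_model8()
  lib <- make_screening_library(
    library_recipe(m, n_active = 20, n_inactive = 40,
                   corrupt_fraction = 0.2, seed = 6))
  oc0 <- screen_library(m, lib, max_omitted = 0)
  expect_equal(screening_metrics(oc0)$sensitivity, 80)
  oc1 <- screen_library(m, lib, max_omitted = 1)
  expect_equal(screening_metrics(oc1)$sensitivity, 100)
})

test_that("excluded entries are skipped during screening", {
  m <- ref_model8()
  lib <- make_screening_library(
    library_recipe(m, n_active = 5, n_inactive = 10, n_excluded = 7,
                   seed = 2))
  oc <- screen_library(m, lib)
  expect_equal(oc$D, 15)
  expect_equal(nrow(oc$entries), 15)
})

test_that("omission never hurts sensitivity; dropping features never hurts either", {
  m <- ref_model8()
  for (seed in 1:3) {
    lib <- make_screening_library(
      library_recipe(m, n_active = 8, n_inactive = 15,
                     corrupt_fraction = 0.25, jitter_sigma = 0.4,
                     seed = seed))
    s0 <- screening_metrics(screen_library(m, lib, max_omitted = 0))
    s1 <- screening_metrics(screen_library(m, lib, max_omitted = 1))
    expect_gte(s1$sensitivity, s0$sensitivity)
    dropped <- edit_model(m, "H1")
    sd0 <- screening_metrics(screen_library(dropped, lib, max_omitted = 0))
    expect_gte(sd0$sensitivity, s0$sensitivity)
    expect_lte(sd0$specificity, s0$specificity + 1e-9)
  }
})

test_that("screening metrics reproduce the tabulated arithmetic", {
  # 2.9% sensitivity from TP = 5 of A = 173; EF 32.3 with D = 5590
  oc1 <- screening_outcome(tp = 5, tn = 5417, A = 173, I = 5417)
  m1 <- screening_metrics(oc1)
  expect_equal(round(m1$sensitivity, 1), 2.9)
  expect_equal(round(m1$ef, 1), 32.3)
  # TP = 136, TN = 5338 -> EF 20.4; the printed 78.1% sensitivity is
  # inconsistent with its own counts (136/173 = 78.6%), which we return
  oc5 <- screening_outcome(tp = 136, tn = 5338, A = 173, I = 5417)
  m5 <- screening_metrics(oc5)
  expect_equal(round(m5$ef, 1), 20.4)
  expect_equal(round(m5$sensitivity, 1), 78.6)
  # identities TP+FN = A, TN+FP = I, EF = sens * D / Htot
  set.seed(1)
  for (i in 1:10) {
    A <- sample(50:200, 1); I <- sample(100:6000, 1)
    tp <- sample(0:A, 1); tn <- sample(0:I, 1)
    oc <- screening_outcome(tp, tn, A, I)
    expect_equal(oc$tp + oc$fn, A)
    expect_equal(oc$tn + oc$fp, I)
    mm <- screening_metrics(oc)
    if (!is.na(mm$ef)) {
      expect_equal(mm$ef, (mm$sensitivity / 100) * oc$D / oc$htot,
                   tolerance = 1e-9)
    }
  }
  # perfect retrieval: EF = D / A
  ocp <- screening_outcome(tp = 173, tn = 5417, A = 173, I = 5417)
  expect_equal(screening_metrics(ocp)$ef, 5590 / 173)
  expect_error(screening_metrics(screening_outcome(0, 0, 0, 10)), "actives")
})

test_that("ROC AUC equals brute-force pair counting and handles ties", {
  # worked 4-entry example: 3 wins, 1 loss out of 4 pairs
  scores <- c(4, 3, 2, 1); labs <- c(TRUE, FALSE, TRUE, FALSE)
  brute <- function(s, l) {
    wins <- 0; tot <- 0
    for (i in which(l)) for (j in which(!l)) {
      tot <- tot + 1
      wins <- wins + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
    }
    wins / tot
  }
  expect_equal(roc_auc(scores, labs), brute(scores, labs))
  expect_equal(roc_auc(scores, labs), 0.75)
  # random instances vs the oracle, with ties and NAs
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(20:200, 1)
    s <- sample(c(rnorm(n - 5), rep(0.3, 5)))
    l <- runif(n) < 0.3
    if (!any(l) || all(l)) next
    s_na <- s; s_na[sample(n, 3)] <- NA
    floor_val <- min(s_na, na.rm = TRUE) - 1
    s_ref <- ifelse(is.na(s_na), floor_val, s_na)
    expect_equal(roc_auc(s_na, l), brute(s_ref, l), tolerance = 1e-12)
  }
  # perfectly separated scores
  expect_equal(roc_auc(c(5, 4, 1, 0), c(TRUE, TRUE, FALSE, FALSE)), 1.0)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("random scores give AUC 1/2 and early AUC behaves at the extremes", {
  set.seed(7)
  n <- 1e5
  s <- rnorm(n); l <- runif(n) < 0.2
  expect_equal(roc_auc(s, l), 0.5, tolerance = 0.01)
  # perfect early retrieval: all actives above all inactives
  sp <- c(rnorm(50) + 100, rnorm(500))
  lp <- c(rep(TRUE, 50), rep(FALSE, 500))
  expect_equal(roc_auc(sp, lp, fraction = 0.015), 1)
  expect_equal(roc_auc(sp, lp, fraction = 1), 1)
  # random early list sits near 1/2
  expect_equal(roc_auc(s, l, fraction = 0.1), 0.5, tolerance = 0.03)
})

test_that("full AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  s <- rnorm(300); l <- runif(300) < 0.25
  ours <- roc_auc(s, l)
  theirs <- as.numeric(pROC::auc(pROC::roc(response = l, predictor = s,
                                           direction = "<", quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-12)
})
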