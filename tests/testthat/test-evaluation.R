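# build a feature_matrix shell with given per-subject segment counts;
# feature values are irrelevant for partition tests
fm_shell <- function(n_subjects_per_class, segs_per_subject, n_feat = 4) {
  ids <- c(sprintf("C%02d", seq_len(n_subjects_per_class[1])),
           sprintf("P%02d", seq_len(n_subjects_per_class[2])))
  labels <- rep(c(0L, 1L), n_subjects_per_class)
  meta <- do.call(rbind, lapply(seq_along(ids), function(i)
    data.frame(subject_id = ids[i], label = labels[i],
               segment_index = seq_len(segs_per_subject) - 1L)))
  x <- matrix(rnorm(nrow(meta) * n_feat), nrow(meta),
              dimnames = list(NULL, sprintf("f%d", seq_len(n_feat))))
  structure(list(x = x, meta = meta), class = "feature_matrix")
}

test_that("subject-unaware folds partition segments within every subject", {
  set.seed(71)
  fm <- fm_shell(c(14, 14), 21)
  folds <- subject_unaware_folds(fm, k = 7)
  expect_length(folds, 7)
  test_sizes <- vapply(folds, function(f) length(f$test), 0L)
  expect_true(all(test_sizes == 28 * 3))
  # disjoint cover
  all_test <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_identical(all_test, seq_len(nrow(fm$meta)))
  # every subject appears on both sides of every fold
  for (f in folds) {
    expect_setequal(unique(fm$meta$subject_id[f$train]),
                    unique(fm$meta$subject_id))
    expect_setequal(unique(fm$meta$subject_id[f$test]),
                    unique(fm$meta$subject_id))
    expect_length(intersect(f$train, f$test), 0)
  }
  expect_error(subject_unaware_folds(fm, k = 1), "k must be")
  expect_error(subject_unaware_folds(fm_shell(c(2, 2), 3), k = 7),
               "segments")
})

test_that("subject-unaware folds partition on random cohort shapes", {
  for (r in 1:10) {
    set.seed(500 + r)
    k <- sample(2:5, 1)
    fm <- fm_shell(c(sample(2:5, 1), sample(2:5, 1)),
                   segs_per_subject = k + sample(0:6, 1))
    folds <- subject_unaware_folds(fm, k = k)
    all_test <- sort(unlist(lapply(folds, `[[`, "test")))
    expect_identical(all_test, seq_len(nrow(fm$meta)))
    for (f in folds)
      expect_identical(sort(c(f$train, f$test)), seq_len(nrow(fm$meta)))
  }
})

test_that("leave-p-subjects-out folds never leak subjects", {
  fm <- fm_shell(c(14, 14), 23)
  folds <- leave_p_subjects_out_folds(fm, k = 7, per_fold = c(2, 2),
                                      seed = 1)
  expect_length(folds, 7)
  for (f in folds) {
    tr_subj <- unique(fm$meta$subject_id[f$train])
    te_subj <- unique(fm$meta$subject_id[f$test])
    expect_length(intersect(tr_subj, te_subj), 0)
    expect_length(tr_subj, 24)
    expect_length(te_subj, 4)
    # class balance of the held-out subjects
    te_lab <- fm$meta$label[match(te_subj, fm$meta$subject_id)]
    expect_identical(sort(te_lab), c(0L, 0L, 1L, 1L))
  }
  # all subjects tested exactly once
  tested <- unlist(lapply(folds, `[[`, "test_subjects"))
  expect_identical(anyDuplicated(tested), 0L)
  expect_length(tested, 28)

  small <- leave_p_subjects_out_folds(fm_shell(c(3, 3), 4), k = 3,
                                      per_fold = c(1, 1), seed = 2)
  expect_length(small, 3)
  expect_error(leave_p_subjects_out_folds(fm_shell(c(3, 3), 4), k = 2,
                                          per_fold = c(2, 2)), "exactly")
})

test_that("ROC/AUC matches hand counts, tie conventions and the pair oracle", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 10), c(0, 0, 1, 1))$auc, 1.0)
  expect_equal(roc_auc(rep(0.5, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")

  for (r in 1:25) {
    set.seed(600 + r)
    n <- sample(4:30, 1)
    labels <- c(0, 1, sample(c(0, 1), n - 2, replace = TRUE))
    scores <- round(runif(n), sample(c(1, 2, 8), 1))  # induce ties sometimes
    expect_equal(roc_auc(scores, labels)$auc, oracle_auc(scores, labels),
                 tolerance = 1e-12)
  }

  # ROC polygon endpoints and trapezoid consistency
  ra <- roc_auc(c(0.2, 0.9, 0.6, 0.3, 0.8), c(0, 1, 1, 0, 1))
  expect_equal(ra$roc$fpr[1], 0); expect_equal(ra$roc$tpr[1], 0)
  expect_equal(ra$roc$fpr[nrow(ra$roc)], 1)
  expect_equal(ra$roc$tpr[nrow(ra$roc)], 1)
  trap <- sum(diff(ra$roc$fpr) *
                (utils::head(ra$roc$tpr, -1) + utils::tail(ra$roc$tpr, -1)) / 2)
  expect_equal(trap, ra$auc, tolerance = 1e-12)
})

test_that("cross-validated runs return one coherent result per fold", {
  set.seed(73)
  fm <- fm_shell(c(3, 3), 6, n_feat = 8)
  # plant an easy signal so forests are non-degenerate
  fm$x[fm$meta$label == 1, 3] <- fm$x[fm$meta$label == 1, 3] + 3
  folds <- leave_p_subjects_out_folds(fm, k = 3, per_fold = c(1, 1),
                                      seed = 5)
  cv <- run_cv(fm, folds, n_trees = 40, min_leaf = 4,
               feature_fraction = 0.5, seed = 7)
  expect_length(cv, 3)
  for (fr in cv) {
    expect_true(fr$auc >= 0 && fr$auc <= 1)
    expect_equal(sum(fr$importances), 1, tolerance = 1e-9)
    expect_identical(length(fr$scores), length(fr$labels))
  }
  # determinism end to end
  cv2 <- run_cv(fm, folds, n_trees = 40, min_leaf = 4,
                feature_fraction = 0.5, seed = 7)
  expect_identical(vapply(cv, `[[`, 0, "auc"), vapply(cv2, `[[`, 0, "auc"))
})

test_that("importance summaries aggregate by minimum and mean", {
  mk_fold <- function(imp) list(fold_index = 1, scores = 1, labels = 1,
                                auc = 1, importances = imp)
  nm <- c("a", "b", "c")
  f1 <- mk_fold(stats::setNames(c(0.1, 0.5, 0.4), nm))
  f2 <- mk_fold(stats::setNames(c(0.0, 0.6, 0.4), nm))
  f3 <- mk_fold(stats::setNames(c(0.1, 0.7, 0.2), nm))
  s <- summarize_importance(structure(list(f1, f2, f3), class = "cv_result"))
  expect_equal(unname(s$i_min), c(0, 0.5, 0.2))
  expect_equal(unname(s$i_avg), c(0.2 / 3, 0.6, 1 / 3), tolerance = 1e-12)
  expect_true(all(s$i_min <= s$i_avg + 1e-12))
  expect_identical(s$rank_avg$feature[1], "b")
  expect_identical(top_features(s, 2, "min"), c("b", "c"))

  single <- summarize_importance(structure(list(f1), class = "cv_result"))
  expect_equal(single$i_min, single$i_avg)

  bad <- structure(list(f1, mk_fold(stats::setNames(c(0.5, 0.5), c("a", "b")))),
                   class = "cv_result")
  expect_error(summarize_importance(bad), "mismatched")
})
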