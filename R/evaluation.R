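#' Subject-unaware K-fold partition
#'
#' Splits each subject's segments into K near-equal chunks (contiguous in
#' time by default) and pools the k-th chunk of every subject into fold
#' k's test set. Every subject therefore contributes segments to both
#' sides of every fold -- the optimistic partitioning in which the model
#' has seen every test subject during training.
#'
#' @param fm a \code{feature_matrix}.
#' @param k number of folds (>= 2); every subject needs >= k segments.
#' @param seed seed used when \code{shuffle = TRUE}.
#' @param shuffle randomize segment order within each subject before
#'   chunking (default FALSE: contiguous temporal blocks, conservative
#'   with respect to autocorrelation).
#' @return a list of K folds, each a list with \code{fold_index},
#'   \code{train} and \code{test} row indices into \code{fm$x}.
#' @export
subject_unaware_folds <- function(fm, k = 7, seed = NULL, shuffle = FALSE) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (k < 2) stop_validation("k must be >= 2")
  meta <- fm$meta
  assignment <- integer(nrow(meta))
  for (sid in unique(meta$subject_id)) {
    idx <- which(meta$subject_id == sid)
    idx <- idx[order(meta$segment_index[idx])]
    if (length(idx) < k)
      stop_validation("subject %s has %d segments; need at least k = %d",
                      sid, length(idx), k)
    if (shuffle) idx <- with_seed(derive_seed(seed, which(unique(meta$subject_id) == sid)),
                                  sample(idx))
    sizes <- rep(length(idx) %/% k, k)
    extra <- length(idx) %% k
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    assignment[idx] <- rep(seq_len(k), times = sizes)
  }
  all_idx <- seq_len(nrow(meta))
  lapply(seq_len(k), function(f)
    list(fold_index = f, train = all_idx[assignment != f],
         test = all_idx[assignment == f]))
}

#' Leave-p-subjects-out K-fold partition
#'
#' Partitions subjects (not segments) into K class-balanced groups; fold
#' k tests on every segment of group k's subjects and trains on the
#' rest, so no subject ever appears on both sides of a fold -- the
#' clinically realistic evaluation of an unseen-subject screen.
#'
#' @param fm a \code{feature_matrix}.
#' @param k number of folds.
#' @param per_fold integer pair: (controls per fold, patients per fold).
#'   The cohort must contain exactly \code{k * per_fold} subjects of each
#'   class.
#' @param seed seed for the random assignment of subjects to folds.
#' @return a list of K folds as in \code{\link{subject_unaware_folds}},
#'   each additionally carrying \code{test_subjects}.
#' @export
leave_p_subjects_out_folds <- function(fm, k = 7, per_fold = c(2, 2),
                                       seed = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  meta <- fm$meta
  subj <- unique(meta[, c("subject_id", "label")])
  controls <- subj$subject_id[subj$label == 0]
  patients <- subj$subject_id[subj$label == 1]
  if (length(controls) != k * per_fold[1] || length(patients) != k * per_fold[2])
    stop_validation("need exactly %d controls and %d patients for k = %d folds of (%d, %d); have (%d, %d)",
                    k * per_fold[1], k * per_fold[2], k, per_fold[1],
                    per_fold[2], length(controls), length(patients))
  with_seed(seed, {
    controls <- sample(controls)
    patients <- sample(patients)
  })
  lapply(seq_len(k), function(f) {
    test_subj <- c(controls[((f - 1) * per_fold[1] + 1):(f * per_fold[1])],
                   patients[((f - 1) * per_fold[2] + 1):(f * per_fold[2])])
    test <- which(meta$subject_id %in% test_subj)
    list(fold_index = f, train = setdiff(seq_len(nrow(meta)), test),
         test = test, test_subjects = test_subj)
  })
}

#' ROC curve and AUC
#'
#' Sweeps all score thresholds (ties grouped) to build the ROC polygon
#' and integrates it by the trapezoidal rule, which equals the
#' normalized Mann-Whitney U statistic under the midrank tie convention.
#'
#' @param scores numeric per-sample scores (higher = more class 1).
#' @param labels binary labels; both classes must be present.
#' @return a list with \code{roc} (data.frame \code{fpr}, \code{tpr})
#'   and \code{auc}.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop_validation("both classes must be present to compute a ROC curve")
  r <- rank(scores)                 # midranks for ties
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)
  o <- order(scores, decreasing = TRUE)
  ys <- labels[o]
  ss <- scores[o]
  keep <- c(ss[-length(ss)] != ss[-1], TRUE)   # last index of each tie group
  tpr <- c(0, cumsum(ys)[keep] / n1)
  fpr <- c(0, cumsum(1 - ys)[keep] / n0)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Run cross-validated forest training and evaluation
#'
#' For every fold: fit the forest on the training rows, score the test
#' rows, compute the fold ROC/AUC and the normalized Gini importances.
#' Deterministic given \code{seed} (each fold uses a seed derived from
#' it).
#'
#' @param fm a \code{feature_matrix}.
#' @param folds partition from \code{\link{subject_unaware_folds}} or
#'   \code{\link{leave_p_subjects_out_folds}}.
#' @param n_trees,min_leaf,feature_fraction forest hyperparameters
#'   (defaults 200, 10, 0.025).
#' @param seed integer seed.
#' @return a list of class \code{cv_result}: one element per fold with
#'   \code{fold_index}, \code{scores}, \code{labels}, \code{auc},
#'   \code{importances}, plus attribute \code{feature_names}.
#' @export
run_cv <- function(fm, folds, n_trees = 200, min_leaf = 10,
                   feature_fraction = 0.025, seed = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  res <- lapply(folds, function(fold) {
    model <- fit_forest(fm$x[fold$train, , drop = FALSE],
                        fm$meta$label[fold$train],
                        n_trees = n_trees, min_leaf = min_leaf,
                        feature_fraction = feature_fraction,
                        seed = derive_seed(seed, fold$fold_index))
    scores <- predict_proba(model, fm$x[fold$test, , drop = FALSE])
    labels <- fm$meta$label[fold$test]
    ra <- roc_auc(scores, labels)
    list(fold_index = fold$fold_index, scores = scores, labels = labels,
         test = fold$test, roc = ra$roc, auc = ra$auc,
         importances = gini_importance(model))
  })
  structure(res, class = "cv_result",
            feature_names = colnames(fm$x))
}

#' Mean AUC over folds
#'
#' Unweighted arithmetic mean of the per-fold AUCs.
#'
#' @param cv a \code{cv_result}.
#' @return scalar mean AUC.
#' @export
mean_auc <- function(cv) {
  mean(vapply(cv, `[[`, 0, "auc"))
}

#' @export
print.cv_result <- function(x, ...) {
  aucs <- vapply(x, `[[`, 0, "auc")
  cat(sprintf("<cv_result> %d folds; AUC per fold: %s; mean %.3f\n",
              length(x), paste(sprintf("%.3f", aucs), collapse = ", "),
              mean(aucs)))
  invisible(x)
}

#' Summarize feature importance across folds
#'
#' Per feature, the minimum importance over folds (is the feature
#' consistently used?) and the mean importance (how much is it used
#' overall?), with descending rankings of both.
#'
#' @param cv a \code{cv_result} (all folds must share one feature
#'   space).
#' @return an object of class \code{importance_summary} with
#'   \code{i_min}, \code{i_avg} (named vectors) and ranking data.frames
#'   \code{rank_min}, \code{rank_avg}.
#' @export
summarize_importance <- function(cv) {
  if (length(cv) < 1) stop_validation("need at least one fold")
  imp <- lapply(cv, `[[`, "importances")
  lens <- vapply(imp, length, 0L)
  if (length(unique(lens)) != 1)
    stop_validation("folds have mismatched feature spaces")
  nms <- lapply(imp, names)
  if (!all(vapply(nms[-1], identical, TRUE, nms[[1]])))
    stop_validation("folds have mismatched feature names")
  mat <- do.call(rbind, imp)
  i_min <- apply(mat, 2, min)
  i_avg <- colMeans(mat)
  rank_of <- function(v) {
    o <- order(v, decreasing = TRUE)
    data.frame(feature = names(v)[o], importance = unname(v[o]),
               stringsAsFactors = FALSE)
  }
  structure(list(i_min = i_min, i_avg = i_avg,
                 rank_min = rank_of(i_min), rank_avg = rank_of(i_avg),
                 n_folds = length(cv)),
            class = "importance_summary")
}

#' Top-k features of an importance summary
#'
#' @param summary an \code{importance_summary}.
#' @param k how many features (default 10).
#' @param by \code{"min"} or \code{"avg"} ranking.
#' @return character vector of feature names, most important first.
#' @export
top_features <- function(summary, k = 10, by = c("min", "avg")) {
  by <- match.arg(by)
  rk <- if (by == "min") summary$rank_min else summary$rank_avg
  utils::head(rk$feature, k)
}

#' @export
print.importance_summary <- function(x, ...) {
  cat(sprintf("<importance_summary> over %d folds; top features by minimum importance:\n",
              x$n_folds))
  print(utils::head(x$rank_min, 10))
  invisible(x)
}
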