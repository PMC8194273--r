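#' Gini impurity of a two-class node
#'
#' \deqn{G = p_A (1 - p_A) + p_B (1 - p_B)} for class fractions
#' \eqn{(p_A, p_B)} summing to 1. Zero for a pure node, maximal (0.5) at
#' a 50/50 mix.
#'
#' @param class_fractions numeric pair of proportions summing to 1.
#' @return the impurity, a non-negative scalar.
#' @export
gini_impurity <- function(class_fractions) {
  p <- as.numeric(class_fractions)
  if (length(p) != 2 || any(p < 0) || any(p > 1))
    stop_validation("class_fractions must be two proportions in [0, 1]")
  if (abs(sum(p) - 1) > 1e-9)
    stop_validation("class fractions must sum to 1 (got %g)", sum(p))
  sum(p * (1 - p))
}

# binary shortcut: G(p) = 2 p (1 - p)
gini_binary <- function(p1) 2 * p1 * (1 - p1)

#' Best axis-aligned split of a node
#'
#' Scans, for every candidate feature, thresholds at the midpoints
#' between consecutive sorted unique values and returns the split
#' minimizing the child-size-weighted Gini impurity, subject to both
#' children holding at least \code{min_leaf} samples. Ties are broken
#' deterministically: lowest feature index, then lowest threshold.
#' Returns \code{NULL} (no-split) when the node is too small, pure, or no
#' admissible split decreases the impurity.
#'
#' @param x numeric sample x feature matrix for the node.
#' @param y binary labels (0/1) for the rows of \code{x}.
#' @param features column indices to consider (default all).
#' @param min_leaf minimum samples per child (the M stopping rule).
#' @return \code{NULL}, or a list with \code{feature} (column index of
#'   \code{x}), \code{threshold} (values <= go left), and
#'   \code{decrease} = parent Gini - weighted child Gini.
#' @export
best_split <- function(x, y, features = seq_len(ncol(x)), min_leaf = 1) {
  n <- length(y)
  if (n < 2 * min_leaf) return(NULL)
  parent <- gini_binary(mean(y))
  if (parent == 0) return(NULL)
  best <- NULL
  for (f in sort(features)) {
    xv <- x[, f]
    o <- order(xv)
    xs <- xv[o]; ys <- y[o]
    i <- seq_len(n - 1)
    ok <- (xs[i] < xs[i + 1]) & (i >= min_leaf) & ((n - i) >= min_leaf)
    if (!any(ok)) next
    c1 <- cumsum(ys)
    i <- i[ok]
    nl <- i; nr <- n - i
    pl <- c1[i] / nl
    pr <- (c1[n] - c1[i]) / nr
    wg <- (nl * gini_binary(pl) + nr * gini_binary(pr)) / n
    j <- which.min(wg)           # ascending thresholds: first min = lowest
    dec <- parent - wg[j]
    if (dec > 0 && (is.null(best) || dec > best$decrease)) {
      cut <- i[j]
      best <- list(feature = f,
                   threshold = (xs[cut] + xs[cut + 1]) / 2,
                   decrease = dec)
    }
  }
  best
}

# grow one Gini decision tree on (x, y); feature indices in the returned
# split log refer to columns of x. n_total is the tree's sample count,
# used to weight impurity decreases by the fraction of samples reaching
# the node (the CART/Breiman importance convention).
grow_tree <- function(x, y, min_leaf, n_total = length(y)) {
  splits <- list()
  rec <- function(idx) {
    ys <- y[idx]
    p1 <- mean(ys)
    s <- if (length(idx) >= 2 * min_leaf && p1 > 0 && p1 < 1)
      best_split(x[idx, , drop = FALSE], ys, min_leaf = min_leaf) else NULL
    if (is.null(s))
      return(list(leaf = TRUE, p1 = p1, n = length(idx)))
    splits[[length(splits) + 1L]] <<-
      c(feature = s$feature, decrease = s$decrease,
        frac = length(idx) / n_total)
    left <- x[idx, s$feature] <= s$threshold
    list(leaf = FALSE, feature = s$feature, threshold = s$threshold,
         left = rec(idx[left]), right = rec(idx[!left]))
  }
  root <- rec(seq_along(y))
  log <- if (length(splits)) do.call(rbind, splits) else
    matrix(numeric(0), 0, 3, dimnames = list(NULL, c("feature", "decrease", "frac")))
  list(root = root, splits = log)
}

# class-1 probability of each row of x under one tree
tree_predict <- function(root, x) {
  out <- numeric(nrow(x))
  rec <- function(node, idx) {
    if (length(idx) == 0) return(invisible())
    if (node$leaf) { out[idx] <<- node$p1; return(invisible()) }
    go_left <- x[idx, node$feature] <= node$threshold
    rec(node$left, idx[go_left])
    rec(node$right, idx[!go_left])
  }
  rec(root, seq_len(nrow(x)))
  out
}

#' Fit a bagged ensemble of Gini decision trees
#'
#' Each tree is trained on a bootstrap resample of the rows (with
#' replacement, same size as the training set) and a uniform random
#' subset of \code{floor(feature_fraction * n_features)} columns drawn
#' without replacement -- note the feature subset is drawn once per
#' \emph{tree}, not per split. Trees are grown greedily with
#' \code{\link{best_split}} until the \code{min_leaf} rule stops them.
#' Fully reproducible given \code{seed}.
#'
#' @param x numeric samples x features matrix (feature names from column
#'   names, if present).
#' @param y binary labels (0/1), one per row.
#' @param n_trees ensemble size (the T hyperparameter; default 200).
#' @param min_leaf minimum samples per leaf (M; default 10).
#' @param feature_fraction fraction of features drawn per tree (P;
#'   default 0.025, i.e. 85 of 3420).
#' @param seed integer seed.
#' @return an object of class \code{forest_model}.
#' @export
fit_forest <- function(x, y, n_trees = 200, min_leaf = 10,
                       feature_fraction = 0.025, seed = NULL) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(y) != nrow(x)) stop_validation("length(y) must match nrow(x)")
  if (length(unique(y)) < 2)
    stop_validation("training labels contain a single class; need both")
  if (!all(y %in% c(0L, 1L))) stop_validation("labels must be 0/1")
  nf <- ncol(x)
  n_sub <- max(1L, as.integer(floor(feature_fraction * nf)))
  n <- nrow(x)
  trees <- with_seed(seed, lapply(seq_len(n_trees), function(b) {
    rows <- sample.int(n, n, replace = TRUE)
    feats <- sort(sample.int(nf, n_sub))
    tr <- grow_tree(x[rows, feats, drop = FALSE], y[rows], min_leaf)
    # remap split/node feature indices from the column slice to the
    # global feature space
    tr$splits[, "feature"] <- feats[tr$splits[, "feature"]]
    remap <- function(node) {
      if (node$leaf) return(node)
      node$feature <- feats[node$feature]
      node$left <- remap(node$left)
      node$right <- remap(node$right)
      node
    }
    list(root = remap(tr$root), features = feats, splits = tr$splits)
  }))
  structure(list(trees = trees, n_trees = n_trees, min_leaf = min_leaf,
                 feature_fraction = feature_fraction,
                 n_features = nf, n_feature_subset = n_sub,
                 feature_names = colnames(x), seed = seed),
            class = "forest_model")
}

#' @export
print.forest_model <- function(x, ...) {
  cat(sprintf("<forest_model> %d trees, min_leaf %d, %d/%d features per tree\n",
              x$n_trees, x$min_leaf, x$n_feature_subset, x$n_features))
  invisible(x)
}

#' Ensemble class-1 probability
#'
#' The mean over trees of each tree's leaf class-1 fraction.
#'
#' @param model a \code{forest_model}.
#' @param x samples x features matrix with the training feature count.
#' @return numeric vector of probabilities in [0, 1].
#' @export
predict_proba <- function(model, x) {
  stopifnot(inherits(model, "forest_model"))
  x <- as.matrix(x)
  if (ncol(x) != model$n_features)
    stop_validation("x has %d features but the model was trained on %d",
                    ncol(x), model$n_features)
  preds <- vapply(model$trees, function(tr) tree_predict(tr$root, x),
                  numeric(nrow(x)))
  if (nrow(x) == 1) mean(preds) else rowMeans(matrix(preds, nrow = nrow(x)))
}

#' Normalized Gini feature importance
#'
#' For every feature, the impurity decreases of all splits on that
#' feature across all trees are summed, each weighted by the fraction of
#' the tree's samples reaching the split node, and the resulting vector
#' is normalized to sum to 1. Features never used by any tree get
#' exactly 0.
#'
#' @param model a fitted \code{forest_model}.
#' @return named non-negative numeric vector summing to 1 (all zeros,
#'   with a warning, if no tree ever split).
#' @export
gini_importance <- function(model) {
  stopifnot(inherits(model, "forest_model"))
  imp <- numeric(model$n_features)
  for (tr in model$trees) {
    if (nrow(tr$splits) == 0) next
    # a feature may split several nodes of one tree: aggregate per
    # feature before the indexed update (which would drop duplicates)
    agg <- rowsum(tr$splits[, "decrease"] * tr$splits[, "frac"],
                  group = tr$splits[, "feature"])
    at <- as.integer(rownames(agg))
    imp[at] <- imp[at] + as.numeric(agg)
  }
  tot <- sum(imp)
  if (tot == 0) {
    warning("no split occurred in any tree; importances are all zero")
  } else {
    imp <- imp / tot
  }
  names(imp) <- model$feature_names %||% sprintf("f%d", seq_along(imp))
  imp
}
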