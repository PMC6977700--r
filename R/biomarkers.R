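#' Stratified, seeded fold assignment
#'
#' @param y Factor (or coercible) of class labels.
#' @param folds Number of folds (default 5).
#' @param seed Integer seed.
#' @return Integer vector of fold indices, one per sample.
#' @export
stratified_folds <- function(y, folds = 5L, seed = 1L) {
  y <- as.factor(y)
  if (min(table(y)) < folds) {
    stop("each class needs at least as many samples as folds")
  }
  set.seed(seed)
  assign <- integer(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Iterative importance-based feature reduction
#'
#' Repeatedly fits a random forest (500 trees), ranks features by
#' out-of-bag permutation importance (mean decrease in OOB accuracy under
#' per-feature permutation) and removes the lowest-scoring third
#' (`floor(current / 3)`, never overshooting `target_k`) until at most
#' `target_k` features remain.
#'
#' @param X Numeric matrix, samples x features, with feature ids as
#'   colnames.
#' @param y Binary factor of sample labels (>= 2 samples per class).
#' @param target_k Number of features to retain (>= 1).
#' @param seed Integer seed.
#' @param ntree Trees per forest (default 500).
#' @return Character vector of surviving feature ids, with a `trace`
#'   attribute (data frame of step, feature count and OOB accuracy).
#' @export
importance_reduction <- function(X, y, target_k, seed = 1L, ntree = 500L) {
  y <- as.factor(y)
  if (nlevels(y) < 2L) stop("'y' must contain two classes")
  if (min(table(y)) < 2L) stop("each class needs at least 2 samples")
  stopifnot(target_k >= 1L)
  feats <- colnames(X)
  if (is.null(feats)) stop("'X' must have feature ids as colnames")
  set.seed(seed)
  trace <- data.frame(step = integer(), n_features = integer(), oob_accuracy = numeric())
  step <- 0L
  while (length(feats) > target_k) {
    step <- step + 1L
    rf <- randomForest::randomForest(X[, feats, drop = FALSE], y,
                                     ntree = ntree, importance = TRUE)
    imp <- randomForest::importance(rf, type = 1L)[, 1L]
    trace <- rbind(trace, data.frame(step = step, n_features = length(feats),
                                     oob_accuracy = 1 - rf$err.rate[ntree, "OOB"]))
    drop_n <- min(max(floor(length(feats) / 3), 1L), length(feats) - target_k)
    feats <- feats[order(imp, decreasing = TRUE)][seq_len(length(feats) - drop_n)]
  }
  attr(feats, "trace") <- trace
  feats
}

#' Enumerate all non-empty subsets of k features
#'
#' Subsets are ordered by size, then lexicographically within size, which
#' fixes the tie-break of [exhaustive_panel_search()] toward fewer features.
#'
#' @param k Number of features (guarded at 16 unless `force = TRUE`).
#' @param force Allow k > 16.
#' @return List of `2^k - 1` integer index vectors.
#' @export
enumerate_subsets <- function(k, force = FALSE) {
  stopifnot(k >= 1L)
  if (k > 16L && !force) {
    stop("k > 16 enumerates more than 65535 subsets; pass force = TRUE to proceed")
  }
  unlist(lapply(seq_len(k), function(s) utils::combn(k, s, simplify = FALSE)),
         recursive = FALSE)
}

# Orient SVM decision values so that larger means the positive class
.oriented_dv <- function(pred, positive) {
  dv <- attr(pred, "decision.values")
  first <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1L]][1L]
  if (first == positive) dv[, 1L] else -dv[, 1L]
}

# Cross-validated accuracy and pooled-decision-value AUC for one feature set
.cv_svm <- function(X, y, fold, kernel, cost) {
  positive <- levels(y)[2L]
  pred_lab <- character(length(y))
  dv <- numeric(length(y))
  for (f in sort(unique(fold))) {
    te <- which(fold == f)
    tr <- which(fold != f)
    Xtr <- X[tr, , drop = FALSE]
    scale_cols <- apply(Xtr, 2L, stats::sd) > 0
    fit <- e1071::svm(Xtr, y[tr], kernel = kernel, cost = cost,
                      gamma = 1 / ncol(X), scale = scale_cols)
    pr <- stats::predict(fit, X[te, , drop = FALSE], decision.values = TRUE)
    pred_lab[te] <- as.character(pr)
    dv[te] <- .oriented_dv(pr, positive)
  }
  auc <- as.numeric(pROC::auc(response = y, predictor = dv, levels = levels(y),
                              direction = "<", quiet = TRUE))
  list(accuracy = mean(pred_lab == as.character(y)), auc = auc, dv = dv)
}

#' Exhaustive feature-subset search under cross-validated SVM
#'
#' Evaluates every non-empty subset of the given features by stratified
#' k-fold cross-validated accuracy of a margin-based kernel classifier
#' (radial-basis SVM, cost 1, kernel width 1/#features, the conventional
#' defaults of this classifier family) and returns the best subset.
#' Ties are broken toward fewer features, then lexicographically. The AUC
#' is computed from decision values pooled across the test folds.
#'
#' @param X Numeric matrix, samples x features, feature ids as colnames.
#' @param y Binary factor of labels; the second level is the positive class.
#' @param features Feature ids to search over (default: all columns;
#'   guarded at 16 unless `force = TRUE`).
#' @param folds Number of CV folds (default 5).
#' @param seed Integer seed (folds and any classifier randomness).
#' @param kernel `"radial"` (default) or `"linear"`.
#' @param cost SVM regularization constant (default 1).
#' @param force Allow more than 16 features.
#' @param top_n Number of best subsets to keep in the score table.
#' @return List of class `panel_result`: `features`, `cv_accuracy`, `auc`,
#'   `fold_assignments`, `classifier_params`, `n_subsets`, and
#'   `subset_scores` (top `top_n` subsets by accuracy).
#' @export
exhaustive_panel_search <- function(X, y, features = colnames(X), folds = 5L,
                                    seed = 1L, kernel = c("radial", "linear"),
                                    cost = 1, force = FALSE, top_n = 100L) {
  kernel <- match.arg(kernel)
  y <- as.factor(y)
  if (nlevels(y) != 2L) stop("'y' must be a binary factor")
  missing <- setdiff(features, colnames(X))
  if (length(missing)) stop("feature(s) absent from X: ", paste(missing, collapse = ", "))
  k <- length(features)
  subsets <- enumerate_subsets(k, force = force)
  fold <- stratified_folds(y, folds = folds, seed = seed)

  acc <- numeric(length(subsets))
  auc <- numeric(length(subsets))
  for (i in seq_along(subsets)) {
    feat <- features[subsets[[i]]]
    res <- .cv_svm(X[, feat, drop = FALSE], y, fold, kernel, cost)
    acc[i] <- res$accuracy
    auc[i] <- res$auc
  }
  best <- which.max(acc) # first maximum: size-then-lex order = desired tie-break
  best_feats <- features[subsets[[best]]]

  ord <- order(-acc, lengths(subsets))
  top <- utils::head(ord, top_n)
  subset_scores <- data.frame(
    features = vapply(subsets[top], function(s) paste(features[s], collapse = ","),
                      character(1L)),
    size = lengths(subsets)[top],
    cv_accuracy = acc[top], auc = auc[top], stringsAsFactors = FALSE
  )
  structure(list(features = best_feats, cv_accuracy = acc[best], auc = auc[best],
                 fold_assignments = fold,
                 classifier_params = list(kernel = kernel, cost = cost,
                                          gamma = 1 / length(best_feats)),
                 n_subsets = length(subsets), subset_scores = subset_scores),
            class = "panel_result")
}

#' @export
print.panel_result <- function(x, ...) {
  cat(sprintf("<panel_result> %d features: %s\n  CV accuracy %.3f, AUC %.3f (%d subsets searched)\n",
              length(x$features), paste(x$features, collapse = ", "),
              x$cv_accuracy, x$auc, x$n_subsets))
  invisible(x)
}

#' Two-cluster hierarchical sample grouping with composition rates
#'
#' Agglomerative clustering (Euclidean distance, complete linkage) of the
#' samples on the panel expression matrix, cut at 2 clusters. For each
#' cluster the per-label composition is reported as percentages (e.g. the
#' rate of cases in the predicted case group).
#'
#' @param X_panel Numeric matrix, samples x panel features.
#' @param true_labels Vector of sample labels (not used for clustering,
#'   only for the composition report).
#' @param linkage Linkage method (default `"complete"`).
#' @return List with `assignment` (cluster index per sample), `counts`
#'   (cluster x label table), and `composition` (row percentages).
#' @export
two_cluster_composition <- function(X_panel, true_labels, linkage = "complete") {
  if (nrow(X_panel) < 2L) stop("need at least 2 samples")
  if (nrow(X_panel) != length(true_labels)) stop("labels must match rows of X_panel")
  hc <- stats::hclust(stats::dist(X_panel), method = linkage)
  cl <- stats::cutree(hc, k = 2L)
  counts <- table(cluster = cl, label = true_labels)
  composition <- prop.table(counts, margin = 1L) * 100
  list(assignment = cl, counts = counts, composition = composition)
}
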