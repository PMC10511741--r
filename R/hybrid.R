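# Deep-feature validation pipeline: RANet FC_3 features -> random-forest
# impurity importance -> top-k selection -> SVM / k-NN / gradient boosting.

#' Random-forest impurity-based feature importance
#'
#' Fits a seeded random forest (default 100 trees, Gini impurity) and returns
#' the normalized mean decrease in impurity per feature together with the
#' across-tree standard deviation.  Trees are grown one at a time (each its
#' own bootstrap sample and mtry draw) so that per-tree importances are
#' available; their mean equals the usual forest-level importance up to
#' normalization.
#'
#' Because mean-decrease-in-impurity shares are diluted when only a random
#' subset of features competes at each split, and this forest's job is to
#' rank features rather than to generalize, every feature is a split
#' candidate by default (`mtry = d`); the bootstrap still randomizes trees.
#'
#' @param features n x d numeric matrix.
#' @param labels Binary labels, length n (both classes present).
#' @param n_trees Number of trees (default 100).
#' @param mtry Number of split candidates per node (default: all features).
#' @param seed Integer seed.
#' @return Object of class `importance_vector`: list with `mean_importance`
#'   (sums to 1), `std_importance`, `feature_names`.
#' @export
rf_feature_importance <- function(features, labels, n_trees = 100,
                                  mtry = ncol(features), seed = 1L) {
  features <- as.matrix(features)
  y <- factor(labels)
  if (nrow(features) < 2) stop_input("need at least 2 samples")
  if (nlevels(droplevels(y)) < 2)
    stop_input("labels are degenerate: both classes must be present")
  d <- ncol(features)
  per_tree <- matrix(0, n_trees, d)
  for (t in seq_len(n_trees)) {
    per_tree[t, ] <- withr::with_seed(derive_seed(seed, t), {
      fit <- randomForest::randomForest(features, y, ntree = 1, mtry = mtry)
      fit$importance[, "MeanDecreaseGini"]
    })
  }
  mu <- colMeans(per_tree)
  tot <- sum(mu)
  if (tot <= 0) stop_input("no impurity decrease recorded; degenerate input")
  fn <- colnames(features) %||% paste0("F", seq_len(d))
  structure(list(mean_importance = setNames(mu / tot, fn),
                 std_importance = setNames(apply(per_tree, 2, sd) / tot, fn),
                 n_trees = n_trees, feature_names = fn),
            class = "importance_vector")
}

#' @export
print.importance_vector <- function(x, ...) {
  ord <- order(-x$mean_importance)
  cat(sprintf("<importance_vector> %d features, %d trees; top 5: %s\n",
              length(x$mean_importance), x$n_trees,
              paste(x$feature_names[head(ord, 5)], collapse = ", ")))
  invisible(x)
}

#' Select the top-k most important features
#'
#' @param importances An `importance_vector` (or bare numeric vector).
#' @param k Number of features to keep (default 12); values above d are
#'   clipped with a warning.  Ties break towards the lower feature index.
#' @return Object of class `selection_result`: `selected_indices` in
#'   descending importance order, `k`.
#' @export
select_top_features <- function(importances, k = 12) {
  mu <- if (inherits(importances, "importance_vector"))
    importances$mean_importance else importances
  if (k < 1) stop_input("k must be >= 1")
  d <- length(mu)
  if (k > d) {
    warning("k exceeds feature count; clipped to ", d)
    k <- d
  }
  ord <- order(-mu, seq_along(mu))
  structure(list(selected_indices = ord[seq_len(k)], k = as.integer(k)),
            class = "selection_result")
}

#' Classical-classifier configuration
#'
#' Hyperparameters follow the study recipe: SVM with RBF kernel and C = 1,
#' k-NN with k = 5 (Euclidean, uniform weights), gradient boosting with 100
#' depth-1 stumps at learning rate 1.
#'
#' @param model `"svm"`, `"knn"` or `"gradient_boosting"` (alias `"gb"`).
#' @param svm_C,svm_kernel SVM cost and kernel.
#' @param knn_k Neighbourhood size.
#' @param gb_estimators,gb_learning_rate,gb_max_depth Boosting parameters.
#' @param seed Integer seed.
#' @return Object of class `ml_config`.
#' @export
ml_config <- function(model = c("svm", "knn", "gradient_boosting", "gb"),
                      svm_C = 1, svm_kernel = "radial", knn_k = 5,
                      gb_estimators = 100, gb_learning_rate = 1,
                      gb_max_depth = 1, seed = 1L) {
  model <- match.arg(model)
  if (model == "gb") model <- "gradient_boosting"
  stopifnot(svm_C > 0, knn_k >= 1, gb_estimators >= 1, gb_learning_rate > 0,
            gb_max_depth >= 1)
  structure(list(model = model, svm_C = svm_C, svm_kernel = svm_kernel,
                 knn_k = as.integer(knn_k),
                 gb_estimators = as.integer(gb_estimators),
                 gb_learning_rate = gb_learning_rate,
                 gb_max_depth = as.integer(gb_max_depth),
                 seed = as.integer(seed)),
            class = "ml_config")
}

#' Train a classical classifier on (deep) features
#'
#' Features are standardized to zero mean / unit variance using training-set
#' statistics (required for the RBF kernel and distance-based k-NN); the
#' same statistics are applied at prediction time.  The RBF gamma follows
#' the 1/(d * var) scaling convention on the standardized features.
#'
#' @param features n x d numeric matrix.
#' @param labels Binary labels (`"normal"` / `"RA"`).
#' @param config An [ml_config()].
#' @return Object of class `thermo_ml` with a [predict.thermo_ml()] method.
#' @export
train_ml_classifier <- function(features, labels, config = ml_config("svm")) {
  x <- as.matrix(features)
  if (any(!is.finite(x))) stop_input("features must be finite")
  y <- factor(labels, levels = thermo_labels)
  center <- colMeans(x)
  scale <- apply(x, 2, sd)
  scale[scale == 0] <- 1
  xs <- scale(x, center, scale)
  fit <- switch(config$model,
    svm = withr::with_seed(config$seed, {
      e1071::svm(xs, y, kernel = config$svm_kernel, cost = config$svm_C,
                 gamma = 1 / (ncol(xs) * max(var(as.vector(xs)), 1e-12)),
                 scale = FALSE, probability = TRUE)
    }),
    knn = list(x = xs, y = y, k = config$knn_k),
    gradient_boosting = withr::with_seed(config$seed, {
      xgboost::xgb.train(
        params = list(max_depth = config$gb_max_depth,
                      eta = config$gb_learning_rate,
                      objective = "binary:logistic", nthread = 1,
                      seed = config$seed),
        data = xgboost::xgb.DMatrix(xs, label = as.numeric(y) - 1),
        nrounds = config$gb_estimators, verbose = 0)
    }))
  structure(list(model = config$model, fit = fit, center = center,
                 scale = scale, config = config, classes = levels(y)),
            class = "thermo_ml")
}

#' @export
print.thermo_ml <- function(x, ...) {
  cat(sprintf("<thermo_ml> %s classifier on %d features\n",
              x$model, length(x$center)))
  invisible(x)
}

#' Predict from a trained classical classifier
#'
#' @param object A `thermo_ml` model.
#' @param newdata n x d feature matrix (raw scale; standardization is applied
#'   internally).
#' @param type `"class"` for labels or `"score"` for a decision score
#'   (higher = more RA-like).
#' @param ... Unused.
#' @return Factor of labels or numeric score vector.
#' @export
predict.thermo_ml <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  xs <- scale(as.matrix(newdata), object$center, object$scale)
  if (object$model == "svm") {
    pr <- predict(object$fit, xs, decision.values = TRUE)
    dv <- drop(attr(pr, "decision.values"))
    # e1071 orients the decision value towards the first class seen in
    # training; flip so that higher means RA
    flip <- if (grepl("^RA", colnames(attr(pr, "decision.values"))[1])) 1 else -1
    if (type == "class") return(factor(as.character(pr), levels = object$classes))
    return(flip * dv)
  }
  if (object$model == "knn") {
    pr <- withr::with_seed(object$config$seed,
      class::knn(object$fit$x, xs, object$fit$y, k = object$fit$k,
                 prob = TRUE))
    if (type == "class") return(factor(as.character(pr), levels = object$classes))
    win <- attr(pr, "prob")
    return(ifelse(pr == "RA", win, 1 - win))   # P(RA)
  }
  p <- predict(object$fit, xgboost::xgb.DMatrix(xs))  # P(class 2) = P(RA)
  if (type == "class")
    return(factor(object$classes[1 + (p > 0.5)], levels = object$classes))
  p
}

#' Run the hybrid with/without-selection comparison
#'
#' Splits the feature rows 70-30 (stratified; subject-wise when `groups` is
#' supplied), computes random-forest importances and the top-k selection on
#' the training fold only, and fits each configured model twice: on all
#' features and on the selected subset.  Standardization statistics also come
#' from the training fold only, so no test-fold information leaks into
#' selection or scaling.
#'
#' @param features n x d feature matrix (e.g. from [extract_features()]).
#' @param labels Binary labels, length n.
#' @param k Number of features to select (default 12).
#' @param models Character vector of model kinds.
#' @param split_seed Seed for the 70-30 split.
#' @param groups Optional grouping vector (e.g. subject ids).
#' @param test_fraction Held-out fraction (default 0.3).
#' @param n_trees Random-forest size for the importance step.
#' @return Object of class `hybrid_report`: data frame `summary` (one row per
#'   model x selection mode), list `reports` of `classification_report`s,
#'   the `selection_result` and `importance_vector`.
#' @export
run_hybrid_experiment <- function(features, labels, k = 12,
                                  models = c("svm", "knn", "gradient_boosting"),
                                  split_seed = 1L, groups = NULL,
                                  test_fraction = 0.3, n_trees = 100) {
  x <- as.matrix(features)
  y <- factor(labels, levels = thermo_labels)
  n <- nrow(x)
  test_idx <- stratified_row_split(y, groups, test_fraction, split_seed)
  tr <- setdiff(seq_len(n), test_idx)
  imp <- rf_feature_importance(x[tr, , drop = FALSE], y[tr], n_trees = n_trees,
                               seed = derive_seed(split_seed, 7L))
  sel <- select_top_features(imp, k)
  rows <- list(); reports <- list()
  for (m in models) {
    for (mode in c("all", "selected")) {
      cols <- if (mode == "all") seq_len(ncol(x)) else sel$selected_indices
      clf <- train_ml_classifier(x[tr, cols, drop = FALSE], y[tr],
                                 ml_config(m, seed = derive_seed(split_seed, 11L)))
      pred <- predict(clf, x[test_idx, cols, drop = FALSE])
      score <- predict(clf, x[test_idx, cols, drop = FALSE], type = "score")
      cm <- confusion_matrix(y[test_idx], pred)
      rep <- classification_metrics(cm)
      rep$auc <- tryCatch(roc_auc(y[test_idx], score)$auc, error = function(e) NA)
      key <- paste(m, mode, sep = "_")
      reports[[key]] <- rep
      rows[[key]] <- data.frame(model = m, selection = mode == "selected",
                                accuracy = rep$accuracy,
                                weighted_f1 = rep$weighted$f1,
                                auc = rep$auc, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(list(summary = out, reports = reports, selection = sel,
                 importance = imp, test_index = test_idx),
            class = "hybrid_report")
}

#' @export
print.hybrid_report <- function(x, ...) {
  cat("Hybrid deep-feature experiment (70-30 split)\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# Stratified (optionally grouped) held-out row indices.
stratified_row_split <- function(y, groups, fraction, seed) {
  idx <- integer(0)
  for (ci in seq_along(levels(y))) {
    rows <- which(y == levels(y)[ci])
    if (!is.null(groups)) {
      units <- unique(groups[rows])
      pick <- withr::with_seed(derive_seed(seed, ci),
                               sample(units, floor(length(units) * fraction)))
      idx <- c(idx, rows[groups[rows] %in% pick])
    } else {
      idx <- c(idx, withr::with_seed(derive_seed(seed, ci),
                                     sample(rows, floor(length(rows) * fraction))))
    }
  }
  sort(idx)
}
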