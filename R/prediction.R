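# Trait binarization (with puppy exclusion) and cross-validated
# gradient-boosted classification of binary traits from microbiome features.

#' Binarize a trait with puppy exclusion
#'
#' Dogs younger than 1 year (not yet behaviorally mature) are removed
#' first. The `"median"` rule resolves to `threshold = ceiling(median)` of
#' the remaining scores with `score >= threshold` labelled high; an explicit
#' numeric threshold is honored as given. Binary flags (e.g. recurrent GI
#' issues) pass through unchanged.
#'
#' @param metadata cohort metadata with `age` and the trait column.
#' @param trait trait column name (a 1-5 score or a logical flag).
#' @param rule `"median"` or a numeric threshold.
#' @return List with `labels` (0/1 integer, high = 1), `ids` (dog ids
#'   used), `rule` (a `grouping_rule`: trait, threshold, group sizes) and
#'   `n_excluded_puppies`.
#' @export
binarize_trait <- function(metadata, trait, rule = "median") {
  stopifnot(trait %in% names(metadata), "age" %in% names(metadata))
  adult <- metadata$age >= 1
  n_puppies <- sum(!adult)
  d <- metadata[adult, , drop = FALSE]
  sc <- d[[trait]]
  keep <- !is.na(sc)
  d <- d[keep, , drop = FALSE]
  sc <- sc[keep]
  if (is.logical(sc)) {
    labels <- as.integer(sc)
    threshold <- NA_real_
  } else {
    threshold <- if (identical(rule, "median")) ceiling(stats::median(sc))
                 else as.numeric(rule)
    labels <- as.integer(sc >= threshold)
  }
  sizes <- c(low = sum(labels == 0), high = sum(labels == 1))
  if (any(sizes == 0)) {
    stop("binarizing '", trait, "' at threshold ", threshold,
         " empties a group (sizes ", sizes["low"], "/", sizes["high"], ")")
  }
  ids <- if ("dog_id" %in% names(d)) d$dog_id else rownames(d)
  list(labels = labels, ids = ids,
       rule = structure(list(trait = trait, threshold = threshold,
                             group_sizes = sizes), class = "grouping_rule"),
       n_excluded_puppies = n_puppies)
}

#' Gradient-boosting booster parameters
#'
#' @param nrounds number of trees.
#' @param max_depth tree depth.
#' @param eta learning rate.
#' @param subsample row subsample fraction per tree.
#' @return Parameter list for [cv_gradient_boosting()].
#' @export
booster_params <- function(nrounds = 200, max_depth = 3, eta = 0.1,
                           subsample = 0.8) {
  list(nrounds = nrounds, max_depth = max_depth, eta = eta,
       subsample = subsample)
}

# deterministic stratified k-fold assignment
stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  if (any(table(factor(fold, levels = seq_len(k)), labels) == 0)) {
    stop("a fold has one class only; reduce k or rebalance")
  }
  fold
}

#' Cross-validated gradient-boosted classification
#'
#' Stratified k-fold split (deterministic under `seed`); a gradient-boosted
#' tree classifier is trained on k-1 folds and scored on the held-out fold.
#' Per-fold ROC AUC (trapezoidal over the score-ranked ROC) and accuracy at
#' a 0.5 probability cutoff are reported with their mean and SD. Both
#' `k = 3` (the AUC protocol) and `k = 5` (the accuracy protocol) are
#' first-class.
#'
#' @param features numeric feature matrix or `feature_table` (the
#'   `sample_id` column is dropped); rows must align with `labels`.
#' @param labels 0/1 integer vector.
#' @param k number of folds (default 3).
#' @param seed integer seed controlling folds and booster subsampling.
#' @param params a [booster_params()] list.
#' @param trait optional trait name recorded in the report.
#' @param n_excluded_puppies recorded in the report.
#' @return A `prediction_report`: list with per-fold `auc` and `accuracy`,
#'   their `mean_auc`/`sd_auc`/`mean_accuracy`/`sd_accuracy`, `k`,
#'   `n_used`, `n_features`, `seed`, `trait`, `n_excluded_puppies`.
#' @export
cv_gradient_boosting <- function(features, labels, k = 3, seed = 1,
                                 params = booster_params(), trait = NA,
                                 n_excluded_puppies = NA_integer_) {
  if (is.data.frame(features)) {
    features <- as.matrix(features[, setdiff(names(features), "sample_id"),
                                   drop = FALSE])
  }
  storage.mode(features) <- "double"
  labels <- as.integer(labels)
  stopifnot(nrow(features) == length(labels), all(labels %in% 0:1))
  if (min(table(labels)) < k) {
    stop("need at least k samples per class (k = ", k, ")")
  }
  fold <- stratified_folds(labels, k, seed)
  auc <- acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    dtrain <- xgboost::xgb.DMatrix(features[tr, , drop = FALSE],
                                   label = labels[tr])
    set.seed(seed + f)
    fit <- xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = params$max_depth, eta = params$eta,
                    subsample = params$subsample, nthread = 1,
                    seed = seed + f),
      data = dtrain, nrounds = params$nrounds, verbose = 0)
    prob <- stats::predict(fit,
                           xgboost::xgb.DMatrix(features[!tr, , drop = FALSE]))
    auc[f] <- roc_auc(labels[!tr], prob)
    acc[f] <- mean((prob >= 0.5) == (labels[!tr] == 1))
  }
  structure(list(trait = trait, n_used = length(labels),
                 n_excluded_puppies = n_excluded_puppies,
                 n_features = ncol(features), k = k, seed = seed,
                 auc = auc, accuracy = acc,
                 mean_auc = mean(auc), sd_auc = stats::sd(auc),
                 mean_accuracy = mean(acc), sd_accuracy = stats::sd(acc)),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf(
    "prediction_report: trait=%s n=%d (%s puppies excluded) %d-fold\n",
    x$trait, x$n_used, x$n_excluded_puppies, x$k))
  cat(sprintf("  ROC AUC  %.3f +/- %.3f\n", x$mean_auc, x$sd_auc))
  cat(sprintf("  accuracy %.3f +/- %.3f\n", x$mean_accuracy, x$sd_accuracy))
  invisible(x)
}

# trapezoidal ROC AUC via pROC; degenerate single-class folds are an error
roc_auc <- function(labels, scores) {
  if (length(unique(labels)) < 2) stop("AUC undefined for one-class fold")
  as.numeric(pROC::auc(pROC::roc(response = labels, predictor = scores,
                                 levels = c(0, 1), direction = "<",
                                 quiet = TRUE)))
}

#' Binarize and evaluate one trait end to end
#'
#' Convenience wrapper: [binarize_trait()] then [cv_gradient_boosting()] on
#' the matching feature rows.
#'
#' @param features a `feature_table` with `sample_id`.
#' @param metadata cohort metadata.
#' @param trait trait name.
#' @param rule grouping rule for [binarize_trait()].
#' @param ... passed to [cv_gradient_boosting()].
#' @return A `prediction_report`.
#' @export
predict_trait <- function(features, metadata, trait, rule = "median", ...) {
  b <- binarize_trait(metadata, trait, rule)
  i <- match(b$ids, features$sample_id)
  if (anyNA(i)) stop("dogs in metadata missing from the feature table")
  cv_gradient_boosting(features[i, , drop = FALSE], b$labels, trait = trait,
                       n_excluded_puppies = b$n_excluded_puppies, ...)
}
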