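#' Build a subject-by-edge feature table
#'
#' Extracts the fiber counts of selected edges for every subject, as the
#' feature matrix for classification.
#'
#' @param stack A [cohort_stack()].
#' @param edges Data frame with columns `i`, `j` (e.g. the jointly
#'   significant edges of the two screens) or integer edge ids.
#' @return A tibble with `subject_id`, `group`, `score`, and one numeric
#'   column per edge named `regionA..regionB`.
#' @export
build_feature_table <- function(stack, edges) {
  stopifnot(inherits(stack, "cohort_stack"))
  em <- edge_matrix(stack)
  if (is.data.frame(edges)) {
    ids <- match(paste(pmin(edges$i, edges$j), pmax(edges$i, edges$j)),
                 paste(em$edges$i, em$edges$j))
    if (anyNA(ids)) stop_input("edge list contains pairs outside the region set")
  } else {
    ids <- as.integer(edges)
  }
  if (length(ids) == 0L) stop_input("feature edge set must be nonempty")
  feats <- em$E[, ids, drop = FALSE]
  colnames(feats) <- paste(em$edges$region_i[ids], em$edges$region_j[ids], sep = "..")
  tibble::as_tibble(cbind(
    tibble::tibble(subject_id = stack$subject_ids,
                   group = stack$group,
                   score = stack$score),
    tibble::as_tibble(feats)))
}

#' Leave-one-out cross-validated linear SVM
#'
#' For each subject in turn: standardize every feature with the training
#' fold's mean and SD (no test leakage at the scaling step), train a linear
#' maximum-margin classifier (hinge loss, C-classification) on the remaining
#' subjects, and predict the held-out subject. The number of folds equals the
#' number of subjects, and predictions are deterministic given fixed features.
#'
#' @param features Data frame with a two-level `group` column and numeric
#'   feature columns (any of `subject_id`, `score` are carried along but not
#'   used as features), as produced by [build_feature_table()].
#' @param regularization SVM cost parameter C (default 1).
#' @param positive_class Group level treated as positive for sensitivity;
#'   default the first level of `group` (SWEDD in the packaged cohorts).
#' @return An `fc_loocv` object: list with `folds` (per-subject tibble of
#'   truth and prediction), `metrics` (one-row tibble from
#'   [confusion_metrics()]), and `settings`.
#' @export
loocv_linear_svm <- function(features, regularization = 1,
                             positive_class = NULL) {
  stopifnot(is.data.frame(features), "group" %in% names(features),
            regularization > 0)
  group <- as.factor(features$group)
  if (nlevels(group) != 2L) stop_input("group must have exactly two levels")
  if (any(table(group) < 2L)) stop_input("each class needs at least 2 subjects")
  positive_class <- positive_class %||% levels(group)[1]
  if (!positive_class %in% levels(group)) {
    stop_input("positive_class '%s' is not a group level", positive_class)
  }
  feat_cols <- setdiff(names(features), c("subject_id", "group", "score"))
  X <- as.matrix(features[, feat_cols, drop = FALSE])
  if (!is.numeric(X)) stop_input("feature columns must be numeric")
  if (anyNA(X)) stop_input("feature table contains missing values")
  n <- nrow(X)
  pred <- character(n)
  for (hold in seq_len(n)) {
    tr <- setdiff(seq_len(n), hold)
    if (length(unique(group[tr])) < 2L) {
      stop_input("training fold %d lost a class", hold)
    }
    mu <- colMeans(X[tr, , drop = FALSE])
    sdv <- apply(X[tr, , drop = FALSE], 2, sd)
    sdv[sdv == 0] <- 1
    Xtr <- scale(X[tr, , drop = FALSE], center = mu, scale = sdv)
    Xte <- scale(X[hold, , drop = FALSE], center = mu, scale = sdv)
    fit <- e1071::svm(Xtr, group[tr], type = "C-classification",
                      kernel = "linear", cost = regularization, scale = FALSE)
    pred[hold] <- as.character(predict(fit, Xte))
  }
  folds <- tibble::tibble(
    fold = seq_len(n),
    subject_id = features[["subject_id"]] %||% sprintf("sub%03d", seq_len(n)),
    truth = as.character(group),
    predicted = pred)
  metrics <- confusion_metrics(pred, as.character(group), positive_class)
  structure(list(folds = folds, metrics = metrics,
                 settings = list(regularization = regularization,
                                 positive_class = positive_class,
                                 n_folds = n,
                                 features = feat_cols)),
            class = "fc_loocv")
}

#' @export
print.fc_loocv <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<fc_loocv> %d folds, %d feature(s); sensitivity %.2f%%, specificity %.2f%%, accuracy %.2f%% (positive class: %s)\n",
              x$settings$n_folds, length(x$settings$features),
              m$sensitivity, m$specificity, m$accuracy,
              x$settings$positive_class))
  invisible(x)
}

#' Confusion counts and derived metrics
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), accuracy = (TP+TN)/n,
#' each expressed in percent and rounded to 2 decimals for reporting.
#'
#' @param predictions,truth Label vectors of equal length with two classes in
#'   `truth`.
#' @param positive_class Label counted as positive.
#' @return One-row tibble with `tp`, `fn`, `tn`, `fp`, `sensitivity`,
#'   `specificity`, `accuracy`.
#' @examples
#' confusion_metrics(rep(c("S", "P"), c(38, 39)),
#'                   rep(c("S", "P"), c(37, 40)), positive_class = "S")
#' @export
confusion_metrics <- function(predictions, truth, positive_class) {
  predictions <- as.character(predictions)
  truth <- as.character(truth)
  if (length(predictions) != length(truth)) stop_input("prediction/truth length mismatch")
  classes <- unique(truth)
  if (length(classes) != 2L) stop_input("truth must contain exactly two classes")
  if (!positive_class %in% classes) {
    stop_input("positive_class '%s' absent from truth", positive_class)
  }
  pos <- truth == positive_class
  tp <- sum(pos & predictions == positive_class)
  fn <- sum(pos & predictions != positive_class)
  tn <- sum(!pos & predictions != positive_class)
  fp <- sum(!pos & predictions == positive_class)
  tibble::tibble(
    tp = tp, fn = fn, tn = tn, fp = fp,
    sensitivity = round(100 * tp / (tp + fn), 2),
    specificity = round(100 * tn / (tn + fp), 2),
    accuracy = round(100 * (tp + tn) / length(truth), 2))
}
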