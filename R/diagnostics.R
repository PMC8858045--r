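# Small-panel SVM diagnostic classifier: training with stored feature
# standardization, stratified k-fold cross-validation with pooled
# out-of-fold predictions, and confusion/ROC evaluation.

#' Confusion-matrix metrics
#'
#' @param tp,fn,tn,fp Non-negative integer counts (positives = cases).
#' @return List with the counts plus `accuracy = (tp+tn)/(tp+tn+fp+fn)`,
#'   `sensitivity = tp/(tp+fn)` and `specificity = tn/(tn+fp)` (`NaN` when a
#'   denominator is zero).
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0)
  list(tp = tp, fn = fn, tn = tn, fp = fp,
       accuracy = (tp + tn) / (tp + tn + fp + fn),
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp))
}

confusion_from_labels <- function(truth, predicted) {
  confusion_metrics(tp = sum(truth == "case" & predicted == "case"),
                    fn = sum(truth == "case" & predicted == "control"),
                    tn = sum(truth == "control" & predicted == "control"),
                    fp = sum(truth == "control" & predicted == "case"))
}

panel_features <- function(expr, panel) {
  missing <- setdiff(panel, rownames(expr$values))
  if (length(missing) > 0) {
    stop("panel gene(s) missing from expression: ",
         paste(missing, collapse = ", "))
  }
  t(expr$values[panel, , drop = FALSE])
}

#' Train a panel SVM classifier
#'
#' Features (the panel genes' expression) are standardized with training-set
#' means and standard deviations, which are stored in the model and reapplied
#' at prediction time. A margin classifier is fit with `e1071::svm`; decision
#' scores are oriented so that higher means more case-like and are exposed
#' for ROC analysis.
#'
#' @param expr A [dg_expression()] with condition labels; both classes must
#'   be present (a single sample per class is tolerated so that small
#'   cross-validation folds can train, though at least 2 per class is what
#'   a real fit needs).
#' @param panel Character vector of panel gene names; default all genes.
#' @param kernel SVM kernel (default `"linear"`).
#' @param cost Soft-margin cost C (default 1).
#' @param seed Integer seed (the linear fit is deterministic; the seed guards
#'   kernels with random initialization).
#' @return Object of class `dg_svm_panel`.
#' @export
train_panel_svm <- function(expr, panel = NULL, kernel = "linear", cost = 1,
                            seed = 1) {
  stopifnot(inherits(expr, "dg_expr"))
  condition <- check_condition(expr$condition, ncol(expr$values))
  if (!any(condition == "case") || !any(condition == "control")) {
    stop("both classes must be present in the training labels")
  }
  if (is.null(panel)) panel <- rownames(expr$values)
  x <- panel_features(expr, panel)
  center <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  xs <- scale(x, center = center, scale = scl)
  y <- factor(condition, levels = c("control", "case"))
  set.seed(seed)
  fit <- e1071::svm(xs, y, kernel = kernel, cost = cost, scale = FALSE)
  dv <- attr(predict(fit, xs, decision.values = TRUE), "decision.values")[, 1]
  flip <- if (mean(dv[y == "case"]) < mean(dv[y == "control"])) -1 else 1
  structure(list(fit = fit, panel = panel, center = center, scale = scl,
                 flip = flip, kernel = kernel, cost = cost, seed = seed),
            class = "dg_svm_panel")
}

#' Predict with a trained panel SVM
#'
#' @param object A `dg_svm_panel` model.
#' @param expr A [dg_expression()] containing at least the panel genes.
#' @param ... Unused.
#' @return Data frame `sample_id`, `score` (oriented decision value, higher =
#'   more case-like), `predicted` (`"case"`/`"control"`).
#' @export
predict.dg_svm_panel <- function(object, expr, ...) {
  x <- panel_features(expr, object$panel)
  xs <- scale(x, center = object$center, scale = object$scale)
  pr <- predict(object$fit, xs, decision.values = TRUE)
  dv <- attr(pr, "decision.values")[, 1] * object$flip
  data.frame(sample_id = rownames(x), score = unname(dv),
             predicted = as.character(unname(pr)))
}

#' Evaluate a panel SVM on labelled samples
#'
#' Applies the stored standardization, predicts every sample, and returns the
#' confusion metrics plus the ROC over the oriented decision scores. When a
#' class is absent from the test labels the corresponding rate is `NaN`.
#'
#' @param model A `dg_svm_panel`.
#' @param expr A [dg_expression()] with condition labels.
#' @return List with `confusion` ([confusion_metrics()] list), `roc`
#'   (points + trapezoidal `auc`; `NULL` if only one class present) and the
#'   per-sample `predictions` data frame.
#' @export
evaluate_panel <- function(model, expr) {
  stopifnot(inherits(model, "dg_svm_panel"))
  condition <- check_condition(expr$condition, ncol(expr$values))
  pred <- predict(model, expr)
  conf <- confusion_from_labels(condition, pred$predicted)
  roc <- if (length(unique(condition)) == 2) {
    roc_curve(pred$score, condition)
  } else NULL
  list(confusion = conf, roc = roc, predictions = pred)
}

#' Stratified k-fold cross-validation of the panel SVM
#'
#' Samples are split into `k` folds stratified by condition; a model is
#' trained on each training split and the held-out samples predicted.
#' Out-of-fold predictions are pooled into a single confusion matrix and a
#' single ROC (matching how whole-cohort classification counts are usually
#' reported). When `k` exceeds the smallest class size some folds lack that
#' class, which is tolerated with a warning.
#'
#' @param expr A [dg_expression()] with condition labels.
#' @param panel Character vector of panel genes; default all genes.
#' @param k Number of folds (default 10; must be >= 2).
#' @param kernel,cost SVM hyperparameters passed to [train_panel_svm()].
#' @param seed Integer seed controlling fold assignment.
#' @return List with pooled `confusion`, `roc`, per-sample `predictions`
#'   (including fold ids), and `folds`.
#' @export
cross_validate <- function(expr, panel = NULL, k = 10, kernel = "linear",
                           cost = 1, seed = 1) {
  stopifnot(inherits(expr, "dg_expr"))
  condition <- check_condition(expr$condition, ncol(expr$values))
  if (k < 2) stop("k must be >= 2")
  n <- ncol(expr$values)
  min_class <- min(table(condition))
  if (k > min_class) {
    warning("k exceeds the smallest class size; some folds will lack a class")
  }
  set.seed(seed)
  fold <- integer(n)
  for (cl in unique(condition)) {
    idx <- which(condition == cl)
    fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  scores <- numeric(n)
  predicted <- character(n)
  for (f in seq_len(k)) {
    test_idx <- which(fold == f)
    if (length(test_idx) == 0) next
    train_idx <- setdiff(seq_len(n), test_idx)
    tr <- dg_expression(expr$values[, train_idx, drop = FALSE],
                        condition[train_idx])
    model <- train_panel_svm(tr, panel = panel, kernel = kernel, cost = cost,
                             seed = seed)
    te <- dg_expression(expr$values[, test_idx, drop = FALSE],
                        condition = NULL)
    pr <- predict(model, te)
    scores[test_idx] <- pr$score
    predicted[test_idx] <- pr$predicted
  }
  conf <- confusion_from_labels(condition, predicted)
  roc <- roc_curve(scores, condition)
  list(confusion = conf, roc = roc,
       predictions = data.frame(sample_id = colnames(expr$values),
                                fold = fold, score = scores,
                                predicted = predicted,
                                condition = condition),
       folds = fold)
}
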