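#' Performance metrics
#'
#' Ten performance measures are supported, five for classification
#' (misclassification error, accuracy, precision, sensitivity, F1) and five
#' for regression (MSE, RMSE, MAE, MAPE, R2). Each metric carries an
#' optimisation direction used by tuning, best-model selection and
#' importance weighting: error-type metrics are minimized, score-type
#' metrics are maximized.
#'
#' Undefined scores (zero denominators, e.g. precision with no positive
#' predictions) are returned as `NA_real_`, the package's missing-score
#' marker; downstream resampled means drop them and record the reduced
#' count rather than silently coercing to 0.
#'
#' @name metrics
NULL

.METRICS <- list(
  err         = list(task = "classification", direction = "minimize"),
  acc         = list(task = "classification", direction = "maximize"),
  precision   = list(task = "classification", direction = "maximize"),
  sensitivity = list(task = "classification", direction = "maximize"),
  f1          = list(task = "classification", direction = "maximize"),
  mse         = list(task = "regression", direction = "minimize"),
  rmse        = list(task = "regression", direction = "minimize"),
  mae         = list(task = "regression", direction = "minimize"),
  mape        = list(task = "regression", direction = "minimize"),
  r2          = list(task = "regression", direction = "maximize")
)

#' Metric specification
#'
#' @param name Lowercase metric name, one of `err`, `acc`, `precision`,
#'   `sensitivity`, `f1`, `mse`, `rmse`, `mae`, `mape`, `r2`.
#' @param epsilon Small positive constant guarding the MAPE denominator
#'   (`max(|y|, epsilon)`); only used by `mape`.
#' @return A `metric_spec` object: list with `name`, `task`, `direction`
#'   (`"minimize"` or `"maximize"`) and `epsilon`.
#' @export
metric_spec <- function(name, epsilon = 1e-8) {
  name <- match.arg(tolower(name), names(.METRICS))
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, epsilon > 0)
  structure(
    list(name = name, task = .METRICS[[name]]$task,
         direction = .METRICS[[name]]$direction, epsilon = epsilon),
    class = "metric_spec"
  )
}

as_metric_spec <- function(metric) {
  if (inherits(metric, "metric_spec")) metric else metric_spec(metric)
}

#' Optimisation direction of a metric
#' @param name Metric name or `metric_spec`.
#' @return `"minimize"` or `"maximize"`.
#' @export
metric_direction <- function(name) as_metric_spec(name)$direction

#' Confusion matrix for a binary view of the labels
#'
#' Builds the 2x2 table of confusion for a designated positive class:
#' TP/FN split the actual positives (P = TP + FN), FP/TN the actual
#' negatives (N = FP + TN); predicted positives PP = TP + FP and predicted
#' negatives PN = FN + TN.
#'
#' @param y_true,y_pred Label vectors of equal length (>= 1).
#' @param positive The label treated as the positive condition; must occur
#'   in the combined label alphabet.
#' @return A `confusion_matrix` object with counts `tp`, `fp`, `tn`, `fn`
#'   and derived margins `p`, `n_neg`, `pp`, `pn`.
#' @export
confusion_matrix <- function(y_true, y_pred, positive) {
  if (length(y_true) == 0L) stop("empty input: no observations to score")
  if (length(y_true) != length(y_pred))
    stop("length mismatch: y_true has ", length(y_true),
         " elements, y_pred has ", length(y_pred))
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  positive <- as.character(positive)
  if (!positive %in% c(y_true, y_pred))
    stop("positive label '", positive, "' not found in the label alphabet")
  tp <- sum(y_true == positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  fp <- sum(y_true != positive & y_pred == positive)
  tn <- sum(y_true != positive & y_pred != positive)
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         p = tp + fn, n_neg = fp + tn, pp = tp + fp, pn = fn + tn,
         positive = positive),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), nrow = 2, byrow = TRUE,
              dimnames = list(c("actual +", "actual -"),
                              c("pred +", "pred -")))
  cat("Confusion matrix (positive = ", x$positive, ")\n", sep = "")
  print(m)
  invisible(x)
}

#' Classification score from a confusion matrix
#'
#' ERR = (FP+FN)/total, ACC = (TP+TN)/total = 1 - ERR,
#' precision = TP/(TP+FP), sensitivity = TP/(TP+FN),
#' F1 = TP / (TP + (FP+FN)/2), the harmonic mean of precision and
#' sensitivity.
#'
#' @param cm A `confusion_matrix`.
#' @param metric Metric name or `metric_spec` (classification metrics only).
#' @return The score, or `NA_real_` when the denominator is zero
#'   (undefined-score condition).
#' @export
classification_score <- function(cm, metric) {
  stopifnot(inherits(cm, "confusion_matrix"))
  spec <- as_metric_spec(metric)
  if (spec$task != "classification")
    stop("metric '", spec$name, "' is a regression metric")
  total <- cm$tp + cm$fp + cm$tn + cm$fn
  if (total == 0L) stop("confusion matrix holds no observations")
  switch(spec$name,
    acc = (cm$tp + cm$tn) / total,
    err = (cm$fp + cm$fn) / total,
    precision = if (cm$pp == 0L) NA_real_ else cm$tp / cm$pp,
    sensitivity = if (cm$p == 0L) NA_real_ else cm$tp / cm$p,
    f1 = {
      denom <- cm$tp + (cm$fp + cm$fn) / 2
      if (denom == 0) NA_real_ else cm$tp / denom
    }
  )
}

#' Regression score
#'
#' MSE = mean squared error, RMSE = sqrt(MSE), MAE = mean absolute error,
#' MAPE = mean of |y - yhat| / max(|y|, epsilon), R2 = 1 - SS_res/SS_tot.
#'
#' @param y_true,y_pred Numeric vectors of equal length (>= 1).
#' @param metric Metric name or `metric_spec` (regression metrics only).
#' @return The score; `NA_real_` for R2 when `y_true` is constant
#'   (undefined-score condition).
#' @export
regression_score <- function(y_true, y_pred, metric) {
  if (length(y_true) == 0L) stop("empty input: no observations to score")
  if (length(y_true) != length(y_pred))
    stop("length mismatch between y_true and y_pred")
  spec <- as_metric_spec(metric)
  if (spec$task != "regression")
    stop("metric '", spec$name, "' is a classification metric")
  res <- y_true - y_pred
  switch(spec$name,
    mse = mean(res^2),
    rmse = sqrt(mean(res^2)),
    mae = mean(abs(res)),
    mape = mean(abs(res) / pmax(abs(y_true), spec$epsilon)),
    r2 = {
      ss_tot <- sum((y_true - mean(y_true))^2)
      if (ss_tot == 0) NA_real_ else 1 - sum(res^2) / ss_tot
    }
  )
}

#' Average per-class scores
#'
#' Macro (unweighted) mean by default; a weighted mean when class counts
#' are supplied. `NA` per-class scores (undefined on a class) are dropped
#' together with their weights.
#'
#' @param per_class_scores Numeric vector of per-class scores (>= 1).
#' @param weights Optional non-negative class counts, same length.
#' @return The averaged score.
#' @export
multiclass_average <- function(per_class_scores, weights = NULL) {
  if (length(per_class_scores) == 0L) stop("no class scores supplied")
  if (is.null(weights)) weights <- rep(1, length(per_class_scores))
  stopifnot(length(weights) == length(per_class_scores), all(weights >= 0))
  ok <- !is.na(per_class_scores)
  if (!any(ok)) return(NA_real_)
  sum(per_class_scores[ok] * weights[ok]) / sum(weights[ok])
}

#' Score predictions with any supported metric
#'
#' Dispatches on the metric's task. Binary classification with a declared
#' positive class scores that class directly; without one (or with > 2
#' classes) class-specific metrics are computed one-vs-rest per class and
#' macro-averaged, while `acc`/`err` are computed on the full label match.
#'
#' @param y_true,y_pred Observed and predicted values.
#' @param metric Metric name or `metric_spec`.
#' @param positive Optional positive class label for binary problems.
#' @return A single score (possibly `NA_real_` if undefined).
#' @export
score <- function(y_true, y_pred, metric, positive = NULL) {
  spec <- as_metric_spec(metric)
  if (spec$task == "regression")
    return(regression_score(as.numeric(y_true), as.numeric(y_pred), spec))
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred))
    stop("length mismatch between y_true and y_pred")
  if (spec$name %in% c("acc", "err")) {
    acc <- mean(y_true == y_pred)
    return(if (spec$name == "acc") acc else 1 - acc)
  }
  classes <- sort(unique(y_true))
  if (!is.null(positive)) {
    return(classification_score(confusion_matrix(y_true, y_pred, positive),
                                spec))
  }
  if (length(classes) <= 2L && length(classes) >= 1L) {
    # binary without a declared positive: use the last sorted level
    pos <- classes[length(classes)]
    return(classification_score(confusion_matrix(y_true, y_pred, pos), spec))
  }
  per_class <- vapply(classes, function(cl) {
    classification_score(confusion_matrix(y_true, y_pred, cl), spec)
  }, numeric(1))
  multiclass_average(per_class)
}
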