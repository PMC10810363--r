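# Independent brute-force oracles used across tests. These deliberately
# loop over observations / configurations rather than reusing any package
# internals.

brute_confusion <- function(y_true, y_pred, positive) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(y_true)) {
    act_pos <- y_true[i] == positive
    pred_pos <- y_pred[i] == positive
    if (act_pos && pred_pos) tp <- tp + 1L
    if (act_pos && !pred_pos) fn <- fn + 1L
    if (!act_pos && pred_pos) fp <- fp + 1L
    if (!act_pos && !pred_pos) tn <- tn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

brute_regression_metric <- function(y, yh, metric, eps = 1e-8) {
  n <- length(y)
  acc <- 0
  for (i in seq_len(n)) {
    acc <- acc + switch(metric,
      mse = (y[i] - yh[i])^2,
      rmse = (y[i] - yh[i])^2,
      mae = abs(y[i] - yh[i]),
      mape = abs(y[i] - yh[i]) / max(abs(y[i]), eps))
  }
  if (metric == "rmse") sqrt(acc / n) else acc / n
}

brute_summary <- function(x, conf = 0.95) {
  n <- length(x)
  m <- sum(x) / n
  v <- sum((x - m)^2) / (n - 1)
  sem <- sqrt(v / n)
  cv <- stats::qt(1 - (1 - conf) / 2, n - 1)
  list(mean = m, sd = sqrt(v), sem = sem,
       ci_low = m - cv * sem, ci_high = m + cv * sem)
}

# filter-then-pick oracle for the 1SE rule: qualifying = within one SE of
# the optimum on the favourable side; returns the first qualifier in the
# supplied simplest-to-most-complex order
brute_one_se <- function(means, ses, direction, simplicity_order) {
  best <- if (direction == "minimize") which.min(means) else which.max(means)
  if (direction == "minimize") {
    thr <- means[best] + ses[best]
    ok <- which(means <= thr)
  } else {
    thr <- means[best] - ses[best]
    ok <- which(means >= thr)
  }
  for (i in simplicity_order) if (i %in% ok) return(i)
  stop("unreachable")
}

# two-stage argmin/argmax oracle for best-model selection
brute_best_model <- function(ci_bounds, scores_by_size, direction) {
  size <- if (direction == "minimize") which.min(ci_bounds)
          else which.max(ci_bounds)
  sc <- scores_by_size[[size]]
  rec <- if (direction == "minimize") which.min(sc) else which.max(sc)
  list(size = size, record = rec)
}

# double-loop FIS oracle
brute_fis <- function(performances, importances, direction, eps = 1e-8) {
  n_models <- length(performances)
  p <- ncol(importances)
  fis <- numeric(p)
  for (i in seq_len(p)) {
    num <- 0; den <- 0
    for (j in seq_len(n_models)) {
      w <- if (direction == "minimize") 1 / (performances[j] + eps)^2
           else performances[j]^2
      num <- num + w * importances[j, i]
      den <- den + w
    }
    fis[i] <- num / den
  }
  fis
}

tiny_classification <- function(n = 80, p = 8, seed = 1) {
  simulate_classification(n, p, 2, effect_size = 2.5, seed = seed)$dataset
}

tiny_regression <- function(n = 80, p = 8, seed = 1) {
  simulate_regression(n, p, 2, noise_sd = 0.5, seed = seed)$dataset
}
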