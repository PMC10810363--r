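#' Learning-method evaluation across training-set sizes
#'
#' The core engine: for every size in a grid and every repeat, the data are
#' randomly split into independent training and held-out sets, the training
#' rows are (optionally) screened, the learner is tuned by inner grid
#' search, refit on the full training split and scored on the training,
#' held-out and full data. Per-size summaries (mean, SD, SEM, confidence
#' interval) quantify both the expected performance and its uncertainty as
#' a function of the training-set size, and an overall best model is
#' selected from the test-set confidence bounds.
#'
#' @name evaluation
NULL

#' Default training-set size grid
#'
#' `n_sizes` sizes from `min_size` (half the observations, rounded up, by
#' default) to `max_size` (`n_obs - 1` by default): equally spaced with
#' step `floor((max_size - min_size) / (n_sizes - 1))`, the last element
#' forced to `max_size`.
#'
#' @param n_obs Number of observations.
#' @param n_sizes Number of grid points (>= 1).
#' @param min_size,max_size Optional overrides of the grid ends.
#' @return Strictly increasing integer vector of training sizes.
#' @export
default_size_grid <- function(n_obs, n_sizes, min_size = NULL,
                              max_size = NULL) {
  n_obs <- as.integer(n_obs); n_sizes <- as.integer(n_sizes)
  stopifnot(n_sizes >= 1L)
  min_size <- as.integer(min_size %||% ceiling(n_obs / 2))
  max_size <- as.integer(max_size %||% (n_obs - 1L))
  if (max_size > n_obs - 1L) stop("max_size must be <= n_obs - 1")
  if (n_sizes == 1L) return(max_size)
  if (max_size <= min_size) stop("max_size must exceed min_size")
  step <- (max_size - min_size) %/% (n_sizes - 1L)
  if (step < 1L) stop("size grid too dense for the available range")
  sizes <- min_size + (seq_len(n_sizes - 1L) - 1L) * step
  c(sizes, max_size)
}

#' Summarize repeated performance scores at one size
#'
#' Mean M, unbiased sample SD s, SEM = s / sqrt(n) and the confidence
#' interval M +/- c * SEM, with the critical value c a Student-t quantile
#' with n - 1 degrees of freedom at the requested confidence level
#' (conservative for small n, converging to the normal value).
#'
#' Missing scores (failed or undefined) reduce the effective n; the number
#' dropped is recorded in `n_missing`. With n = 1 the CI is undefined
#' (`NA`) and flagged.
#'
#' @param performances Numeric vector of per-repeat scores (may contain
#'   `NA`).
#' @param confidence Confidence level in (0, 1), default 0.95.
#' @return A `size_summary`: list with `mean`, `sd`, `sem`, `ci_low`,
#'   `ci_high`, `critical_value`, `n`, `n_missing`, `confidence`.
#' @export
summarize_size <- function(performances, confidence = 0.95) {
  stopifnot(confidence > 0, confidence < 1)
  n_missing <- sum(is.na(performances))
  x <- performances[!is.na(performances)]
  n <- length(x)
  if (n == 0L) stop("no scores to summarize")
  m <- mean(x)
  if (n == 1L) {
    out <- list(mean = m, sd = NA_real_, sem = NA_real_, ci_low = NA_real_,
                ci_high = NA_real_, critical_value = NA_real_, n = n,
                n_missing = n_missing, confidence = confidence)
  } else {
    s <- stats::sd(x)
    sem <- s / sqrt(n)
    cv <- stats::qt(1 - (1 - confidence) / 2, df = n - 1L)
    out <- list(mean = m, sd = s, sem = sem, ci_low = m - cv * sem,
                ci_high = m + cv * sem, critical_value = cv, n = n,
                n_missing = n_missing, confidence = confidence)
  }
  structure(out, class = "size_summary")
}

# one (size, repeat) task: split -> screen -> tune -> refit -> score
run_task <- function(task, dataset, spec, scheme, metric, screening,
                     inner, tuning_rule, task_seed, keep_model = FALSE) {
  set.seed(task_seed)
  n <- nrow(dataset$X)
  split <- draw_split(n, task$size, scheme, repeat_id = task$repeat_index)
  Xtr <- dataset$X[split$train_idx, , drop = FALSE]
  ytr <- dataset$y[split$train_idx]
  strata_tr <- if (!is.null(scheme$strata)) scheme$strata[split$train_idx]

  sel <- seq_len(ncol(dataset$X))
  if (!is.null(screening))
    sel <- screen_features(Xtr, ytr, screening, seed = task_seed)
  Xtr_s <- Xtr[, sel, drop = FALSE]

  tr <- grid_search(spec, Xtr_s, ytr, inner = inner, metric = metric,
                    seed = task_seed, strata = strata_tr)
  config <- if (tuning_rule == "one_se") tr$one_se_config else tr$best_config
  model <- fit(spec, config, Xtr_s, ytr, seed = task_seed)

  feats <- colnames(dataset$X)
  presence <- stats::setNames(rep(0L, length(feats)), feats)
  sgn <- presence
  stability <- stats::setNames(rep(0, length(feats)), feats)
  presence[colnames(Xtr_s)] <- model$presence
  sgn[colnames(Xtr_s)] <- model$sign
  stability[colnames(Xtr_s)] <- tuning_stability(tr)

  slice_score <- function(rows) {
    pred <- stats::predict(model, dataset$X[rows, sel, drop = FALSE])
    score(dataset$y[rows], pred, metric)
  }
  record <- list(
    size_index = task$size_index, repeat_id = task$repeat_index,
    size = task$size, configuration = config,
    tuning_rule = tuning_rule,
    selected_features = colnames(Xtr_s),
    train_score = slice_score(split$train_idx),
    test_score = slice_score(split$held_out_idx),
    full_score = slice_score(seq_len(n)),
    presence = presence, sign = sgn, stability = stability,
    n_screened = length(sel),
    train_idx = split$train_idx, held_out_idx = split$held_out_idx,
    tuning_split_digests = tr$split_digests,
    task_seed = task_seed, failed = FALSE)
  if (keep_model) record$model <- model
  record
}

#' Evaluate a learning method by repeated random sampling
#'
#' @param dataset A dataset from [dataset()], [load_dataset()] or a
#'   simulator.
#' @param spec A [learner_spec()] matching the dataset's task.
#' @param sizes Integer vector of training-set sizes (see
#'   [default_size_grid()]).
#' @param n_repeats Number of repeated samples per size (constant across
#'   sizes).
#' @param metric Primary metric (name or [metric_spec()]); drives tuning,
#'   selection and importance weighting.
#' @param scheme A [sampling_scheme()] (subsample or bootstrap).
#' @param screening Optional [screening_config()]; applied to training rows
#'   only, inside each split.
#' @param inner Inner resampling for tuning, an [inner_scheme()].
#' @param tuning_rule `"best"` (refit the optimal configuration, default)
#'   or `"one_se"` (refit the 1SE configuration).
#' @param confidence Confidence level of the per-size intervals.
#' @param seed Master seed; one sub-seed per (size, repeat) task is derived
#'   from it, so results are identical for any `workers`.
#' @param workers Number of parallel workers (forked; the evaluation is
#'   embarrassingly parallel over tasks).
#' @return A `method_evaluation`: `records` (one per size x repeat),
#'   `summaries` (tibble: size x slice with mean/sd/sem/ci), `best`
#'   (selected record index and, in `best_model`, the refit model), plus
#'   the full configuration echo.
#' @export
evaluate_method <- function(dataset, spec, sizes, n_repeats = 10L,
                            metric = if (spec$task == "classification") "acc"
                                     else "mse",
                            scheme = sampling_scheme("subsample",
                                                     strata = dataset$strata),
                            screening = NULL, inner = inner_scheme(),
                            tuning_rule = c("best", "one_se"),
                            confidence = 0.95, seed = 1L, workers = 1L) {
  stopifnot(inherits(spec, "learner_spec"))
  tuning_rule <- match.arg(tuning_rule)
  metric <- as_metric_spec(metric)
  if (metric$task != spec$task)
    stop("metric '", metric$name, "' does not match the task '", spec$task,
         "'")
  sizes <- as.integer(sizes)
  stopifnot(all(diff(sizes) > 0) || length(sizes) == 1L)
  n <- nrow(dataset$X)
  if (max(sizes) > n - 1L) stop("largest size must be <= n_obs - 1")

  tasks <- list()
  for (i in seq_along(sizes))
    for (j in seq_len(n_repeats))
      tasks[[length(tasks) + 1L]] <-
        list(size_index = i, repeat_index = j, size = sizes[i])
  task_seeds <- derive_seeds(seed, length(tasks))

  worker <- function(ti) {
    tryCatch(
      run_task(tasks[[ti]], dataset, spec, scheme, metric, screening,
               inner, tuning_rule, task_seeds[ti]),
      error = function(e) list(size_index = tasks[[ti]]$size_index,
                               repeat_id = tasks[[ti]]$repeat_index,
                               size = tasks[[ti]]$size, failed = TRUE,
                               error = conditionMessage(e)))
  }
  records <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_along(tasks), worker, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(seq_along(tasks), worker)
  }

  n_failed <- sum(vapply(records, function(r) isTRUE(r$failed), logical(1)))
  if (n_failed > 0L)
    warning(n_failed, " of ", length(records), " model fits failed and are ",
            "excluded from the summaries")

  summaries <- summarize_records(records, sizes, confidence)

  ev <- structure(list(
    dataset_digest = dataset_digest(list(dataset$X, dataset$y)),
    task = spec$task, learner = spec, metric = metric$name,
    direction = metric$direction, sizes = sizes, n_repeats = n_repeats,
    scheme = scheme$scheme, allocation = scheme$allocation,
    screening = screening, inner = unclass(inner),
    tuning_rule = tuning_rule, confidence = confidence, seed = seed,
    feature_names = colnames(dataset$X),
    records = records, summaries = summaries, n_failed = n_failed),
    class = "method_evaluation")

  best <- tryCatch(select_best_model(ev), error = function(e) NULL)
  ev$best <- best
  if (!is.null(best)) {
    # refit the selected record deterministically to retain a usable model
    task <- list(size_index = best$size_index, repeat_index = best$repeat_id,
                 size = best$size)
    rec <- run_task(task, dataset, spec, scheme, metric, screening, inner,
                    tuning_rule, best$task_seed, keep_model = TRUE)
    ev$best_model <- rec$model
  }
  ev
}

summarize_records <- function(records, sizes, confidence) {
  rows <- list()
  for (i in seq_along(sizes)) {
    recs <- Filter(function(r) r$size_index == i && !isTRUE(r$failed),
                   records)
    for (slice in c("train", "test", "full")) {
      if (length(recs) == 0L) next
      scores <- vapply(recs, function(r) r[[paste0(slice, "_score")]],
                       numeric(1))
      sm <- summarize_size(scores, confidence)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        size_index = i, size = sizes[i], slice = slice, mean = sm$mean,
        sd = sm$sd, sem = sm$sem, ci_low = sm$ci_low, ci_high = sm$ci_high,
        n = sm$n, n_missing = sm$n_missing)
    }
  }
  do.call(rbind, rows)
}

#' Select the overall best model
#'
#' Two-stage rule on the test slice: first the training-set size with the
#' most favourable confidence bound — the lowest upper bound of the CI for
#' minimized metrics, the highest lower bound for maximized ones — then,
#' at that size, the single model with the optimal test score. Train/full
#' summaries never drive selection.
#'
#' @param ev A `method_evaluation`.
#' @param metric Metric name (must be the evaluation's metric).
#' @return The winning record (with `record_index` added).
#' @export
select_best_model <- function(ev, metric = ev$metric) {
  stopifnot(identical(metric, ev$metric))
  direction <- ev$direction
  test <- ev$summaries[ev$summaries$slice == "test", , drop = FALSE]
  if (nrow(test) == 0L) stop("all records failed; nothing to select")
  bound <- if (direction == "minimize") test$ci_high else test$ci_low
  # n = 1 leaves the CI undefined; fall back to the mean as the bound
  bound[is.na(bound)] <- test$mean[is.na(bound)]
  best_size_index <- test$size_index[
    if (direction == "minimize") which.min(bound) else which.max(bound)]
  idx <- which(vapply(ev$records, function(r)
    r$size_index == best_size_index && !isTRUE(r$failed), logical(1)))
  scores <- vapply(ev$records[idx], function(r) r$test_score, numeric(1))
  if (all(is.na(scores))) stop("no scored record at the selected size")
  pick <- idx[if (direction == "minimize") which.min(scores)
              else which.max(scores)]
  rec <- ev$records[[pick]]
  rec$record_index <- pick
  rec
}

#' Evaluate a single model on an external dataset
#'
#' Scores an already-fitted model on user-provided external data; no
#' refitting occurs. The external feature space must cover the model's
#' features by name.
#'
#' @param model A `trained_model`.
#' @param X_ext Matrix with named columns.
#' @param y_ext External response.
#' @param metrics Character vector of metric names.
#' @return Tibble with columns `metric`, `value`.
#' @export
evaluate_model_external <- function(model, X_ext, y_ext,
                                    metrics = if (model$spec$task ==
                                      "classification")
                                      c("acc", "err", "precision",
                                        "sensitivity", "f1")
                                    else c("mse", "rmse", "mae", "mape",
                                           "r2")) {
  pred <- stats::predict(model, X_ext)
  tibble::tibble(
    metric = metrics,
    value = unname(vapply(metrics, function(m) score(y_ext, pred, m),
                          numeric(1))))
}
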