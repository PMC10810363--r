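#' Grid-search tuning with the one-standard-error rule
#'
#' The training split is further split into inner training/validation sets
#' (tenfold cross-validation by default); every configuration of the grid
#' is scored on the identical inner splits (paired comparison) and the one
#' with the optimal mean validation score is the best configuration. A
#' second, one-standard-error (1SE) configuration is also selected: the
#' simplest configuration whose mean score lies within one standard error
#' of the optimum, trading a statistically indistinguishable loss for lower
#' complexity and potentially better generalisation.
#'
#' @name tuning
NULL

#' Inner resampling scheme for tuning
#'
#' @param scheme `"kfold"` (default) or `"subsample"`.
#' @param k Folds for kfold (default 10).
#' @param n_inner Number of inner splits for subsample mode.
#' @param train_fraction Training fraction for subsample mode.
#' @return An `inner_scheme` list.
#' @export
inner_scheme <- function(scheme = c("kfold", "subsample"), k = 10L,
                         n_inner = 10L, train_fraction = 0.8) {
  structure(list(scheme = match.arg(scheme), k = as.integer(k),
                 n_inner = as.integer(n_inner),
                 train_fraction = train_fraction),
            class = "inner_scheme")
}

make_inner_splits <- function(n_obs, inner, strata = NULL) {
  if (inner$scheme == "kfold") {
    k <- min(inner$k, n_obs)
    kfold_splits(n_obs, k, strata = strata)
  } else {
    size <- max(1L, min(n_obs - 1L,
                        as.integer(round(inner$train_fraction * n_obs))))
    sch <- sampling_scheme("subsample", strata = strata)
    lapply(seq_len(inner$n_inner), function(r)
      draw_split(n_obs, size, sch, repeat_id = r))
  }
}

split_digest <- function(s) paste(s$train_idx, collapse = ",")

#' Grid search over hyperparameter configurations
#'
#' @param spec A [learner_spec()].
#' @param X_train,y_train The (already screened) training split.
#' @param inner An [inner_scheme()]; inner splits are drawn once and reused
#'   for every configuration.
#' @param metric Metric name or [metric_spec()].
#' @param seed Integer seed controlling the inner splits and the fits.
#' @param strata Optional strata labels for the inner splits.
#' @return A `tuning_result`: per-configuration `table` (tibble: config id,
#'   mean, se, n_scores), `configs`, `best_config` / `best_id`,
#'   `one_se_config` / `one_se_id`, `m` (total inner fits),
#'   `presence_counts` (per-feature count over the m inner fits),
#'   `split_digests`, and `scores` (configs x splits matrix).
#' @export
grid_search <- function(spec, X_train, y_train, inner = inner_scheme(),
                        metric, seed = 1L, strata = NULL) {
  metric <- as_metric_spec(metric)
  configs <- grid_configurations(spec)
  stopifnot(length(configs) >= 1L)
  n <- nrow(X_train)
  splits <- with_seed(seed, make_inner_splits(n, inner, strata = strata))
  m_splits <- length(splits)
  fit_seeds <- derive_seeds(seed, length(configs) * m_splits)

  scores <- matrix(NA_real_, nrow = length(configs), ncol = m_splits)
  presence_counts <- stats::setNames(rep(0L, ncol(X_train)),
                                     colnames(X_train))
  m_models <- 0L
  for (ci in seq_along(configs)) {
    for (si in seq_len(m_splits)) {
      s <- splits[[si]]
      sd_i <- fit_seeds[(ci - 1L) * m_splits + si]
      mod <- tryCatch(
        fit(spec, configs[[ci]], X_train[s$train_idx, , drop = FALSE],
            y_train[s$train_idx], seed = sd_i),
        error = function(e) NULL)
      if (is.null(mod)) next
      m_models <- m_models + 1L
      presence_counts <- presence_counts + mod$presence
      pred <- stats::predict(mod, X_train[s$held_out_idx, , drop = FALSE])
      scores[ci, si] <- score(y_train[s$held_out_idx], pred, metric)
    }
  }

  means <- apply(scores, 1L, function(r) mean(r, na.rm = TRUE))
  ses <- apply(scores, 1L, function(r) {
    r <- r[!is.na(r)]
    if (length(r) < 2L) return(0)
    stats::sd(r) / sqrt(length(r))
  })
  n_scores <- rowSums(!is.na(scores))
  valid <- which(n_scores > 0L)
  if (length(valid) == 0L) stop("all configurations failed during tuning")
  if (length(valid) < length(configs))
    message("tuning: ", length(configs) - length(valid),
            " configuration(s) dropped (all inner scores undefined)")

  simp_order <- order_by_simplicity(spec, configs)
  opt <- if (metric$direction == "minimize") {
    valid[which.min(means[valid])]
  } else valid[which.max(means[valid])]
  # ties on the mean: prefer the simplest qualifying configuration
  tied <- valid[!is.na(means[valid]) & means[valid] == means[opt]]
  if (length(tied) > 1L) opt <- tied[order(match(tied, simp_order))][1L]

  ose <- one_se_config(means, ses, metric$direction, simp_order,
                       valid = valid, best = opt)

  structure(list(
    table = tibble::tibble(config = seq_along(configs), mean = means,
                           se = ses, n_scores = n_scores),
    configs = configs,
    best_id = opt, best_config = configs[[opt]],
    one_se_id = ose, one_se_config = configs[[ose]],
    m = m_models, presence_counts = presence_counts,
    split_digests = vapply(splits, split_digest, character(1)),
    scores = scores, metric = metric$name),
    class = "tuning_result")
}

#' One-standard-error configuration
#'
#' Among configurations whose mean score is within one standard error of
#' the optimum (best mean + SE_best for minimized metrics, best mean -
#' SE_best for maximized ones), returns the simplest per the declared
#' complexity order. The optimum itself always qualifies.
#'
#' @param means,ses Per-configuration mean scores and standard errors.
#' @param direction `"minimize"` or `"maximize"`.
#' @param simplicity_order Integer permutation of configurations from
#'   simplest to most complex.
#' @param valid Indices of configurations eligible (default all with finite
#'   mean).
#' @param best Index of the optimal configuration (default recomputed).
#' @return Index of the 1SE configuration.
#' @export
one_se_config <- function(means, ses, direction, simplicity_order,
                          valid = which(is.finite(means)), best = NULL) {
  if (length(valid) == 0L) stop("no valid configuration scores")
  if (is.null(best)) {
    best <- if (direction == "minimize") valid[which.min(means[valid])]
            else valid[which.max(means[valid])]
  }
  thr_se <- ses[best]
  qualifies <- if (direction == "minimize")
    valid[means[valid] <= means[best] + thr_se]
  else
    valid[means[valid] >= means[best] - thr_se]
  # simplest qualifying configuration
  simplicity_order[simplicity_order %in% qualifies][1L]
}

#' Per-feature tuning stability
#'
#' The frequency of each feature across all `m` models fitted during the
#' tuning of one outer model.
#'
#' @param tr A `tuning_result`.
#' @return Named numeric vector in [0, 1].
#' @export
tuning_stability <- function(tr) {
  stopifnot(inherits(tr, "tuning_result"), tr$m >= 1L)
  tr$presence_counts / tr$m
}
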