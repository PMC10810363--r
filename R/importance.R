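#' Performance-weighted feature importance
#'
#' A global feature importance score (FIS) is aggregated over every model
#' fitted during an evaluation (all sizes, all repeats): the weighted mean
#' of per-model importances, where the weight of model j squares its
#' performance so better models count more —
#' `weight_j = performance_j^2` for maximized metrics and
#' `weight_j = 1 / (performance_j + epsilon)^2` for minimized ones — and
#' the per-model importance of feature i is
#' `presence_ij * sign_ij * stability_ij`, combining whether the model used
#' the feature, the sign of its coefficient (where applicable) and how
#' frequently the feature appeared across the models fitted during tuning.
#'
#' @name importance
NULL

#' Weight of one model from its performance
#'
#' @param performance Finite performance value (non-negative when
#'   minimized).
#' @param direction `"minimize"` or `"maximize"`.
#' @param epsilon Small positive guard against division by zero.
#' @return Strictly positive weight.
#' @export
model_weight <- function(performance, direction, epsilon = 1e-8) {
  stopifnot(is.finite(performance))
  if (direction == "minimize") {
    stopifnot(performance >= 0)
    1 / (performance + epsilon)^2
  } else {
    performance^2
  }
}

#' Per-feature importance of one model
#'
#' @param presence 0/1 vector (feature used by the model).
#' @param sign -1/0/+1 vector (coefficient sign where applicable).
#' @param stability Per-feature tuning stability in [0, 1].
#' @return Numeric vector in [-1, 1]; exactly 0 wherever the feature is
#'   absent.
#' @export
model_importance <- function(presence, sign, stability) {
  stopifnot(all(presence %in% c(0L, 1L)), all(sign %in% c(-1L, 0L, 1L)),
            all(stability >= 0 & stability <= 1))
  presence * sign * stability
}

#' Aggregate importance across an evaluation
#'
#' @param ev A `method_evaluation`.
#' @param metric Metric name feeding the weights (default the evaluation's
#'   primary metric).
#' @param slice Data slice whose performance feeds the weights (default
#'   `"test"`).
#' @param epsilon Guard constant of the minimized-metric weight.
#' @return An `importance_table` tibble: `feature`, `fis`, `support`
#'   (number of models with presence 1), `mean_stability`.
#' @export
aggregate_importance <- function(ev, metric = ev$metric, slice = "test",
                                 epsilon = 1e-8) {
  stopifnot(identical(metric, ev$metric),
            slice %in% c("train", "test", "full"))
  direction <- ev$direction
  recs <- Filter(function(r) !isTRUE(r$failed), ev$records)
  recs <- Filter(function(r) !is.na(r[[paste0(slice, "_score")]]), recs)
  if (length(recs) == 0L) stop("no non-failed model with a defined score")
  feats <- ev$feature_names
  num <- stats::setNames(rep(0, length(feats)), feats)
  support <- stats::setNames(rep(0L, length(feats)), feats)
  stab_sum <- num
  wsum <- 0
  for (r in recs) {
    w <- model_weight(r[[paste0(slice, "_score")]], direction, epsilon)
    imp <- model_importance(r$presence[feats], r$sign[feats],
                            r$stability[feats])
    num <- num + w * imp
    wsum <- wsum + w
    support <- support + r$presence[feats]
    stab_sum <- stab_sum + r$stability[feats]
  }
  stopifnot(wsum > 0)
  tibble::tibble(feature = feats, fis = unname(num / wsum),
                 support = unname(support),
                 mean_stability = unname(stab_sum / length(recs)))
}
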