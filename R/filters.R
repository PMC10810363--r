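#' Unsupervised feature filtering
#'
#' Response-blind screening applied once, before any sampling, so no
#' information from held-out rows or from the response can leak into the
#' retained feature set (none of these functions accepts the response).
#' Three rules are available:
#'
#' * missing-ratio: drop features whose fraction of missing values exceeds
#'   a cutoff;
#' * threshold: keep features exceeding a signal threshold in at least a
#'   minimum number of samples (typical for expression data, where the
#'   threshold is often each sample's median expression);
#' * variability: keep the most variable features by SD, IQR or MAD.
#'
#' All three return a logical keep-mask over columns, stable under feature
#' permutation.
#'
#' @name filters
NULL

#' Missing-ratio filter
#'
#' @param X Numeric matrix (samples x features).
#' @param cutoff Maximum tolerated fraction of missing values in [0, 1];
#'   a feature is kept iff missing count / n_obs <= cutoff.
#' @return Named logical keep mask over features.
#' @export
filter_missing_ratio <- function(X, cutoff) {
  stopifnot(is.matrix(X), cutoff >= 0, cutoff <= 1)
  ratio <- colMeans(is.na(X))
  mask <- ratio <= cutoff
  if (!any(mask)) warning("missing-ratio filter removed every feature")
  stats::setNames(mask, colnames(X))
}

#' Threshold filter
#'
#' Keeps a feature iff its value strictly exceeds the threshold in at least
#' `min_samples` samples. `threshold = "median"` compares each value against
#' its own sample's median across features (the per-sample median mode
#' common for expression matrices); equality counts as failing. Missing
#' values never exceed the threshold.
#'
#' @param X Numeric matrix (samples x features).
#' @param threshold A number, or `"median"` for per-sample medians.
#' @param min_samples Required number of exceeding samples; a value in
#'   (0, 1] is read as a fraction of samples (default 0.5 = half the
#'   samples, rounded up).
#' @return Named logical keep mask.
#' @export
filter_threshold <- function(X, threshold, min_samples = 0.5) {
  stopifnot(is.matrix(X))
  n <- nrow(X)
  if (is.numeric(min_samples) && length(min_samples) == 1L &&
      min_samples > 0 && min_samples <= 1 && min_samples != as.integer(min_samples)) {
    min_samples <- ceiling(min_samples * n)
  } else if (identical(min_samples, 1)) {
    # ambiguous 1: treat as a count of one sample
    min_samples <- 1L
  }
  min_samples <- as.integer(min_samples)
  if (min_samples > n) stop("min_samples exceeds the number of samples")
  if (identical(threshold, "median")) {
    thr <- apply(X, 1L, stats::median, na.rm = TRUE)
    exceeds <- sweep(X, 1L, thr, ">")
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1L)
    exceeds <- X > threshold
  }
  exceeds[is.na(exceeds)] <- FALSE
  mask <- colSums(exceeds) >= min_samples
  stats::setNames(mask, colnames(X))
}

#' Variability filter
#'
#' Ranks features by a variability measure across samples and retains the
#' `ceiling(keep * p)` most variable ones (or `keep` of them when `keep` is
#' an integer count > 1). Ties and the ordering of equal measures are broken
#' by original feature order. Missing values are ignored when computing the
#' measure; a constant feature has measure 0 and ranks last.
#'
#' @param X Numeric matrix (samples x features).
#' @param measure `"sd"`, `"iqr"` or `"mad"`.
#' @param keep Fraction in (0, 1] or integer count of features to retain.
#' @param mad_constant Scale factor of the MAD; 1.4826 (normal consistency)
#'   by default.
#' @return Named logical keep mask.
#' @export
filter_variability <- function(X, measure = c("sd", "iqr", "mad"), keep,
                               mad_constant = 1.4826) {
  stopifnot(is.matrix(X), ncol(X) >= 1L)
  measure <- match.arg(measure)
  p <- ncol(X)
  n_keep <- if (keep > 1) as.integer(keep) else {
    stopifnot(keep > 0, keep <= 1)
    as.integer(ceiling(keep * p))
  }
  if (n_keep > p) stop("keep exceeds the number of features")
  v <- apply(X, 2L, function(col) {
    col <- col[!is.na(col)]
    if (length(col) < 2L) return(0)
    switch(measure,
           sd = stats::sd(col),
           iqr = stats::IQR(col),
           mad = stats::mad(col, constant = mad_constant))
  })
  ord <- order(-v, seq_len(p))
  mask <- rep(FALSE, p)
  mask[ord[seq_len(n_keep)]] <- TRUE
  stats::setNames(mask, colnames(X))
}
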