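#' Random partitioning of observations
#'
#' Three resampling schemes split observations into a training set and a
#' held-out set: sampling without replacement (`subsample`), sampling with
#' replacement (`bootstrap`, held-out = out-of-bag complement), and k-fold
#' cross-validation (`kfold`). With a stratification variable the draw is
#' stratified: `proportionate` allocation preserves the strata fractions of
#' the full observation set, `balanced` allocation equalises strata counts
#' in the sample.
#'
#' @name sampling
NULL

#' Sampling scheme
#'
#' @param scheme One of `"subsample"`, `"bootstrap"`, `"kfold"`.
#' @param strata Optional per-observation stratum labels.
#' @param allocation `"none"`, `"proportionate"` or `"balanced"`;
#'   balanced is only valid for subsample/bootstrap.
#' @param k Number of folds (kfold only), 2 <= k <= n_obs - 1 (k = n_obs,
#'   leave-one-out, is accepted when requested explicitly).
#' @return A `sampling_scheme` object.
#' @export
sampling_scheme <- function(scheme = c("subsample", "bootstrap", "kfold"),
                            strata = NULL,
                            allocation = c("none", "proportionate", "balanced"),
                            k = 10L) {
  scheme <- match.arg(scheme)
  allocation <- match.arg(allocation)
  if (allocation == "balanced" && scheme == "kfold")
    stop("balanced allocation is only available for subsample and bootstrap")
  if (!is.null(strata) && allocation == "none") allocation <- "proportionate"
  structure(list(scheme = scheme, strata = strata,
                 allocation = allocation, k = as.integer(k)),
            class = "sampling_scheme")
}

#' Allocate a sample size across strata
#'
#' Proportionate mode preserves strata fractions via the largest-remainder
#' method (ties broken by stratum order in `strata_counts`); balanced mode
#' starts every stratum at `floor(size / n_strata)` and hands the remainder
#' to strata in decreasing availability order, capping at availability and
#' redistributing any overflow.
#'
#' @param strata_counts Named vector of per-stratum availabilities (>= 1).
#' @param size Total number of observations to allocate.
#' @param mode `"proportionate"` or `"balanced"`.
#' @param replace Whether the downstream draw is with replacement; without
#'   replacement an allocation exceeding a stratum's availability is an
#'   error under balanced mode.
#' @return Named integer vector of allocated counts summing to `size`.
#' @export
stratified_allocation <- function(strata_counts, size,
                                  mode = c("proportionate", "balanced"),
                                  replace = FALSE) {
  mode <- match.arg(mode)
  labs <- names(strata_counts)
  if (is.null(labs)) stop("strata_counts must be named")
  strata_counts <- stats::setNames(as.integer(strata_counts), labs)
  if (any(strata_counts < 1L)) stop("every stratum must have count >= 1")
  total <- sum(strata_counts)
  size <- as.integer(size)
  if (!replace && size > total)
    stop("size exceeds the total number of observations")
  ns <- length(strata_counts)

  if (mode == "proportionate") {
    quota <- size * strata_counts / total
    alloc <- floor(quota)
    rem <- size - sum(alloc)
    if (rem > 0L) {
      frac <- quota - alloc
      # largest remainder first; ties broken by stratum order
      ord <- order(-frac, seq_len(ns))
      alloc[ord[seq_len(rem)]] <- alloc[ord[seq_len(rem)]] + 1L
    }
    if (!replace && any(alloc > strata_counts)) {
      # repair: cap and push the excess to strata with spare availability
      over <- sum(pmax(alloc - strata_counts, 0L))
      alloc <- pmin(alloc, strata_counts)
      spare <- strata_counts - alloc
      ord <- order(-spare, seq_len(ns))
      for (i in ord) {
        if (over == 0L) break
        add <- min(over, spare[i])
        alloc[i] <- alloc[i] + add
        over <- over - add
      }
    }
  } else {
    alloc <- rep(size %/% ns, ns)
    rem <- size - sum(alloc)
    if (rem > 0L) {
      ord <- order(-strata_counts, seq_len(ns))
      alloc[ord[seq_len(rem)]] <- alloc[ord[seq_len(rem)]] + 1L
    }
    if (!replace && any(alloc > strata_counts))
      stop("balanced allocation: requested per-stratum count exceeds ",
           "availability in stratum '",
           labs[which(alloc > strata_counts)[1L]], "'")
  }
  stats::setNames(as.integer(alloc), labs)
}

new_split <- function(train_idx, held_out_idx, size_requested, scheme,
                      repeat_id = 1L) {
  structure(list(train_idx = as.integer(train_idx),
                 held_out_idx = as.integer(held_out_idx),
                 size_requested = as.integer(size_requested),
                 scheme = scheme, repeat_id = as.integer(repeat_id)),
            class = "split")
}

#' Draw one training/held-out split
#'
#' `subsample` draws `size` indices without replacement (held-out = the
#' complement, required non-empty so `size <= n_obs - 1`); `bootstrap`
#' draws `size` indices with replacement and holds out the out-of-bag
#' complement of the distinct training indices. With strata the per-stratum
#' counts follow [stratified_allocation()].
#'
#' Uses the session RNG; pass `seed` for a self-contained deterministic
#' draw.
#'
#' @param n_obs Number of observations.
#' @param size Requested training-set size.
#' @param scheme A [sampling_scheme()] (subsample or bootstrap).
#' @param repeat_id Identifier stored on the split.
#' @param seed Optional integer seed applied locally.
#' @return A `split` object.
#' @export
draw_split <- function(n_obs, size, scheme = sampling_scheme("subsample"),
                       repeat_id = 1L, seed = NULL) {
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  n_obs <- as.integer(n_obs); size <- as.integer(size)
  if (scheme$scheme == "kfold")
    stop("use kfold_splits() for k-fold cross-validation")
  replace <- scheme$scheme == "bootstrap"
  if (size < 1L) stop("size must be >= 1")
  if (!replace && size > n_obs - 1L)
    stop("size must be <= n_obs - 1 for subsampling (held-out set must be ",
         "non-empty)")
  if (replace && size > n_obs)
    stop("bootstrap size must be <= n_obs")

  if (!is.null(scheme$strata)) {
    strata <- scheme$strata
    if (length(strata) != n_obs) stop("strata length must equal n_obs")
    counts <- table(strata)
    labs <- names(counts)
    alloc <- stratified_allocation(
      stats::setNames(as.integer(counts), labs), size,
      mode = if (scheme$allocation == "balanced") "balanced"
             else "proportionate",
      replace = replace)
    if (!replace && any(alloc > as.integer(counts)))
      stop("allocation exceeds a stratum's availability")
    train <- integer(0)
    for (lab in labs) {
      pool <- which(strata == lab)
      k <- alloc[[lab]]
      if (k > 0L)
        train <- c(train, pool[sample.int(length(pool), k, replace = replace)])
    }
  } else {
    train <- sample.int(n_obs, size, replace = replace)
  }
  held <- setdiff(seq_len(n_obs), unique(train))
  new_split(train, held, size, scheme$scheme, repeat_id)
}

#' k-fold cross-validation splits
#'
#' Partitions the observations into k folds whose sizes differ by at most
#' one; each split holds out one fold and trains on the combined remaining
#' k - 1 folds. Under stratification observations are dealt round-robin to
#' folds within each stratum (a stratum smaller than k leaves some folds
#' without it; a warning is issued).
#'
#' @param n_obs Number of observations.
#' @param k Number of folds, 2 <= k <= n_obs.
#' @param strata Optional stratum labels of length `n_obs`.
#' @param seed Optional integer seed applied locally.
#' @return List of `k` `split` objects whose held-out sets partition
#'   `1:n_obs`.
#' @export
kfold_splits <- function(n_obs, k, strata = NULL, seed = NULL) {
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  n_obs <- as.integer(n_obs); k <- as.integer(k)
  if (k < 2L || k > n_obs)
    stop("k must satisfy 2 <= k <= n_obs")
  fold_of <- integer(n_obs)
  if (is.null(strata)) {
    perm <- sample.int(n_obs)
    fold_of[perm] <- rep_len(seq_len(k), n_obs)
  } else {
    if (length(strata) != n_obs) stop("strata length must equal n_obs")
    counts <- table(strata)
    if (any(counts < k))
      warning("stratum smaller than k: some folds will lack it")
    offset <- sample.int(k, 1L) - 1L
    for (lab in names(counts)) {
      pool <- which(strata == lab)
      pool <- pool[sample.int(length(pool))]
      fold_of[pool] <- ((offset + seq_along(pool) - 1L) %% k) + 1L
      offset <- offset + length(pool)
    }
  }
  lapply(seq_len(k), function(f) {
    held <- which(fold_of == f)
    new_split(which(fold_of != f), held, n_obs - length(held), "kfold",
              repeat_id = f)
  })
}

#' Export splits as a two-column table for audit
#'
#' @param splits List of `split` objects.
#' @return A data.frame with columns `repeat_id`, `index` (1-based training
#'   indices).
#' @export
splits_table <- function(splits) {
  do.call(rbind, lapply(splits, function(s) {
    data.frame(repeat_id = s$repeat_id, index = s$train_idx)
  }))
}
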