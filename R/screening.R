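#' Supervised feature screening
#'
#' Response-aware screening run strictly inside each training split (after
#' sampling, before tuning/training), so held-out rows never influence the
#' selected feature set. Two tests are available: an empirical-Bayes
#' moderated two-sample t-test, which shrinks per-feature variances toward
#' a common prior and stabilises inference when features vastly outnumber
#' samples, and a permutation test of a user-chosen statistic.
#'
#' @name screening
NULL

# Newton solve of trigamma(y) = x, x > 0 (monotone decreasing); the same
# root is needed to moment-match the prior df of the variance distribution.
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(Inf)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (i in 1:60) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, 2L)
      y <- y + dif
      if (abs(dif) / y < 1e-10) break
    }
    y
  }, numeric(1))
}

# Moment-matching fit of the scaled-F prior for sample variances s^2 with d
# residual df: returns prior df d0 and prior variance s0^2. Works on
# z = log(s^2); E[z] and Var[z] involve digamma/trigamma of d/2 and d0/2.
fit_variance_prior <- function(s2, d) {
  s2 <- s2[is.finite(s2)]
  s2 <- pmax(s2, 0)
  m <- stats::median(s2)
  if (m == 0)
    stop("zero pooled variance in all features: prior inestimable")
  s2 <- pmax(s2, 1e-5 * m)  # offset exact zeros away from log(0)
  n <- length(s2)
  if (n < 2L) return(list(d0 = 0, s02 = NA_real_))
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(d / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- mean(s2)
  }
  list(d0 = d0, s02 = s02)
}

#' Empirical-Bayes moderated two-sample t-test
#'
#' For each feature, the two-group pooled sample variance `s^2` (d =
#' n1 + n2 - 2 residual df) is shrunk toward a prior `s0^2` with prior df
#' `d0`, both estimated by moment matching on the log sample variances
#' across features: the posterior variance is
#' `(d0 * s0^2 + d * s^2) / (d0 + d)` and the moderated t is the mean
#' difference divided by `s_tilde * sqrt(1/n1 + 1/n2)`, referred to a
#' t-distribution with `d + d0` degrees of freedom. With `prior_df = 0`
#' the statistic reduces to the classical pooled two-sample t; as
#' `prior_df` grows the denominator variance tends to the prior.
#'
#' @param X_train Numeric matrix (samples x features), training rows only.
#' @param y_train Binary group labels (factor/character/logical), one per
#'   row; each group needs >= 2 observations.
#' @param prior_df Optional override of the estimated prior df `d0` (e.g.
#'   0 for the ordinary t). `NULL` estimates it from the data.
#' @return A `screening_result`: list with per-feature `statistic`,
#'   `p_value`, `df_total`, the prior (`d0`, `s02`) and `method`.
#' @export
moderated_t <- function(X_train, y_train, prior_df = NULL) {
  stopifnot(is.matrix(X_train))
  y <- as.character(y_train)
  groups <- sort(unique(y))
  if (length(groups) != 2L)
    stop("moderated_t requires exactly two groups; got ", length(groups))
  i1 <- y == groups[1L]; i2 <- y == groups[2L]
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2L || n2 < 2L)
    stop("each group needs >= 2 observations (got ", n1, " and ", n2, ")")
  d <- n1 + n2 - 2
  m1 <- colMeans(X_train[i1, , drop = FALSE])
  m2 <- colMeans(X_train[i2, , drop = FALSE])
  ss1 <- colSums(sweep(X_train[i1, , drop = FALSE], 2L, m1)^2)
  ss2 <- colSums(sweep(X_train[i2, , drop = FALSE], 2L, m2)^2)
  s2 <- (ss1 + ss2) / d

  if (is.null(prior_df)) {
    prior <- tryCatch(fit_variance_prior(s2, d), error = function(e) {
      if (grepl("prior inestimable", conditionMessage(e))) stop(e)
      warning("variance-prior fit failed; falling back to ordinary t")
      list(d0 = 0, s02 = NA_real_)
    })
  } else {
    stopifnot(prior_df >= 0)
    prior <- list(
      d0 = prior_df,
      s02 = if (prior_df > 0) fit_variance_prior(s2, d)$s02 else NA_real_)
  }
  d0 <- prior$d0; s02 <- prior$s02
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2))
             else if (d0 == 0) s2
             else (d0 * s02 + d * s2) / (d0 + d)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  stat <- (m1 - m2) / se
  stat[m1 == m2] <- 0            # zero mean difference => 0 even if se = 0
  df_total <- d + d0
  p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(stat))
       else 2 * stats::pt(-abs(stat), df = df_total)
  structure(list(statistic = stats::setNames(stat, colnames(X_train)),
                 p_value = stats::setNames(p, colnames(X_train)),
                 df_total = df_total, d0 = d0, s02 = s02,
                 method = "moderated_t"),
            class = "screening_result")
}

all_binary_assignments <- function(y) {
  # distinct relabelings of a two-group vector preserving group sizes
  groups <- sort(unique(y))
  n <- length(y)
  n1 <- sum(y == groups[1L])
  combs <- utils::combn(n, n1)
  lapply(seq_len(ncol(combs)), function(j) {
    lab <- rep(groups[2L], n)
    lab[combs[, j]] <- groups[1L]
    lab
  })
}

#' Permutation test per feature
#'
#' The response labels are permuted (features fixed) and the base statistic
#' recomputed `B` times; the two-sided Monte-Carlo p-value uses the add-one
#' estimator `p = (1 + #{|stat_perm| >= |stat_obs|}) / (B + 1)`, never
#' exactly zero. With `exhaustive = TRUE` (binary response) all distinct
#' label assignments are enumerated and the exact p-value
#' `#{|stat_perm| >= |stat_obs|} / N` is returned (the identity assignment
#' is among the N, so p >= 1/N).
#'
#' @param X_train Numeric matrix (samples x features), training rows only.
#' @param y_train Response labels.
#' @param base_statistic Function `(X, y) -> per-feature statistic`;
#'   default is the difference in group means (binary response).
#' @param B Number of random permutations (>= 1).
#' @param exhaustive Enumerate all distinct assignments instead of sampling.
#' @param seed Optional integer seed applied locally.
#' @return A `screening_result` with `statistic` (observed) and `p_value`.
#' @export
permutation_test <- function(X_train, y_train, base_statistic = NULL,
                             B = 1000L, exhaustive = FALSE, seed = NULL) {
  stopifnot(is.matrix(X_train), B >= 1L)
  if (length(unique(y_train)) < 2L)
    stop("degenerate constant response: nothing to permute")
  if (is.null(base_statistic)) {
    base_statistic <- function(X, y) {
      y <- as.character(y)
      g <- sort(unique(y))
      if (length(g) != 2L)
        stop("default statistic requires a binary response")
      colMeans(X[y == g[1L], , drop = FALSE]) -
        colMeans(X[y == g[2L], , drop = FALSE])
    }
  }
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  obs <- base_statistic(X_train, y_train)
  if (exhaustive) {
    perms <- all_binary_assignments(as.character(y_train))
    hits <- rep(0L, length(obs))
    for (lab in perms) {
      st <- base_statistic(X_train, lab)
      hits <- hits + (abs(st) >= abs(obs))
    }
    p <- hits / length(perms)
  } else {
    hits <- rep(0L, length(obs))
    for (b in seq_len(B)) {
      lab <- y_train[sample.int(length(y_train))]
      st <- base_statistic(X_train, lab)
      hits <- hits + (abs(st) >= abs(obs))
    }
    p <- (1 + hits) / (B + 1)
  }
  structure(list(statistic = stats::setNames(obs, colnames(X_train)),
                 p_value = stats::setNames(p, colnames(X_train)),
                 method = if (exhaustive) "permutation_exact" else "permutation"),
            class = "screening_result")
}

#' Screening configuration
#'
#' @param method `"moderated_t"`, `"permutation"` or `"both"`.
#' @param alpha Significance cutoff on p-values (default 0.05); `alpha = 1`
#'   keeps every screened feature.
#' @param top_k Cap on the number of selected features (by |statistic|),
#'   default 500; also the fallback pool when nothing passes `alpha`.
#' @param combine How to combine the two tests when `method = "both"`:
#'   `"intersection"` (default) or `"union"`.
#' @param permutations Number of permutations B for the permutation test.
#' @return A `screening_config` list.
#' @export
screening_config <- function(method = c("moderated_t", "permutation", "both"),
                             alpha = 0.05, top_k = 500L,
                             combine = c("intersection", "union"),
                             permutations = 1000L) {
  structure(list(method = match.arg(method), alpha = alpha,
                 top_k = as.integer(top_k), combine = match.arg(combine),
                 permutations = as.integer(permutations)),
            class = "screening_config")
}

select_from_result <- function(res, alpha, top_k) {
  pass <- which(res$p_value < alpha)
  if (length(pass) == 0L) {
    # fallback: top-k by |statistic|, logged via message
    message("screening: no feature passed alpha = ", alpha,
            "; falling back to top-", top_k, " by |statistic|")
    pass <- seq_along(res$statistic)
  }
  if (length(pass) > top_k)
    pass <- pass[order(-abs(res$statistic[pass]), pass)[seq_len(top_k)]]
  sort(unname(pass))
}

run_test_multigroup <- function(X, y, runner) {
  # binary: run directly; multiclass: one-vs-rest, minimum p per feature
  groups <- sort(unique(as.character(y)))
  if (length(groups) <= 2L) return(runner(X, as.character(y)))
  res <- NULL
  for (g in groups) {
    yy <- ifelse(as.character(y) == g, g, "rest")
    r <- runner(X, yy)
    if (is.null(res)) res <- r
    else {
      take <- r$p_value < res$p_value
      res$p_value[take] <- r$p_value[take]
      res$statistic[take] <- r$statistic[take]
    }
  }
  res
}

#' Select features on a training split
#'
#' Runs the configured test(s) on the training rows only and applies the
#' selection rule: p-value < alpha, capped at `top_k` features by
#' |statistic|; with both tests the two selections are intersected (or
#' united) per configuration. An empty selection falls back to the top-k
#' features by |statistic| with a logged message. Multiclass responses are
#' screened one-vs-rest with the minimum p per feature.
#'
#' @param X_train Training feature matrix.
#' @param y_train Training response (classification labels).
#' @param config A [screening_config()].
#' @param seed Optional seed for the permutation test.
#' @return Sorted integer indices of selected features (in the supplied,
#'   i.e. post-filter, feature space).
#' @export
screen_features <- function(X_train, y_train, config = screening_config(),
                            seed = NULL) {
  sel <- list()
  if (config$method %in% c("moderated_t", "both")) {
    res <- run_test_multigroup(X_train, y_train,
                               function(X, y) moderated_t(X, y))
    sel$mod_t <- select_from_result(res, config$alpha, config$top_k)
  }
  if (config$method %in% c("permutation", "both")) {
    res <- run_test_multigroup(X_train, y_train, function(X, y) {
      permutation_test(X, y, B = config$permutations, seed = seed)
    })
    sel$perm <- select_from_result(res, config$alpha, config$top_k)
  }
  if (length(sel) == 1L) return(sel[[1L]])
  if (config$combine == "intersection") sort(intersect(sel$mod_t, sel$perm))
  else sort(union(sel$mod_t, sel$perm))
}
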