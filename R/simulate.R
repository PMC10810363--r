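#' Synthetic data generators
#'
#' Two generators make every stage of the pipeline testable without
#' external downloads. Both return the dataset together with the ground
#' truth (`SimTruth`): the informative feature indices and their effects,
#' so screening, selection and importance recovery can be checked against
#' known answers.
#'
#' `simulate_classification` emulates a case/control design with a small
#' set of informative features among many standard-Gaussian noise features:
#' informative features have a between-class mean shift of `effect_size`
#' standard deviations. `simulate_regression` emulates a sparse linear
#' model `y = X beta + N(0, noise_sd)` with standard-Gaussian predictors.
#'
#' @name synthetic-data
NULL

#' Construct a dataset
#'
#' @param X Numeric matrix (samples x features); feature names are taken
#'   from (or assigned to) its columns.
#' @param y Response vector, one element per row of `X` (factor/character
#'   labels for classification, numeric for regression).
#' @param strata Optional per-sample stratum labels.
#' @param task `"classification"` or `"regression"`; inferred from `y` when
#'   omitted.
#' @return An `ml_dataset` object.
#' @export
dataset <- function(X, y, strata = NULL, task = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("feature_", seq_len(ncol(X)))
  if (anyDuplicated(colnames(X))) stop("feature names must be unique")
  if (is.null(rownames(X)))
    rownames(X) <- paste0("sample_", seq_len(nrow(X)))
  if (anyDuplicated(rownames(X))) stop("sample ids must be unique")
  if (nrow(X) != length(y))
    stop("row count of X (", nrow(X), ") must equal length of y (",
         length(y), ")")
  if (is.null(task))
    task <- if (is.numeric(y)) "regression" else "classification"
  if (task == "classification") y <- as.factor(y)
  if (!is.null(strata) && length(strata) != nrow(X))
    stop("strata length must equal the number of samples")
  structure(list(X = X, y = y, strata = strata, task = task),
            class = "ml_dataset")
}

#' @export
print.ml_dataset <- function(x, ...) {
  cat("<ml_dataset> ", nrow(x$X), " samples x ", ncol(x$X), " features, ",
      x$task, "\n", sep = "")
  if (x$task == "classification") {
    tb <- table(x$y)
    cat("  classes:", paste0(names(tb), " (", tb, ")", collapse = ", "), "\n")
  }
  cat("  missing fraction:", round(mean(is.na(x$X)), 4), "\n")
  invisible(x)
}

#' Simulate a classification dataset with planted informative features
#'
#' @param n_obs Number of samples.
#' @param n_features Total number of features.
#' @param n_informative Number of informative features (first
#'   `n_informative` columns).
#' @param effect_size Between-class mean shift of informative features, in
#'   SD units (noise features are N(0,1) in both classes). With more than
#'   two classes the class means are equally spaced with adjacent gap
#'   `effect_size`.
#' @param class_fractions Class membership probabilities (sum to 1);
#'   labels are drawn iid, so realized counts are multinomial.
#' @param seed Integer seed; the generator is deterministic per seed.
#' @return List with `dataset` (an `ml_dataset`, strata = class labels) and
#'   `truth` (informative indices, per-class means, seed).
#' @export
simulate_classification <- function(n_obs, n_features, n_informative,
                                    effect_size,
                                    class_fractions = c(0.5, 0.5),
                                    seed = 1L) {
  stopifnot(n_informative <= n_features,
            abs(sum(class_fractions) - 1) < 1e-8)
  n_classes <- length(class_fractions)
  if (any(class_fractions * n_obs < 1))
    stop("a class has fewer than one expected member")
  with_seed(seed, {
    labels <- sample(seq_len(n_classes), n_obs, replace = TRUE,
                     prob = class_fractions)
    X <- matrix(stats::rnorm(n_obs * n_features), n_obs, n_features)
    # centred, equally spaced class means for the informative block
    mus <- effect_size * (seq_len(n_classes) - (n_classes + 1) / 2)
    if (n_informative > 0L)
      X[, seq_len(n_informative)] <-
        X[, seq_len(n_informative), drop = FALSE] + mus[labels]
    colnames(X) <- paste0("feature_", seq_len(n_features))
    y <- factor(paste0("class_", labels),
                levels = paste0("class_", seq_len(n_classes)))
    ds <- dataset(X, y, strata = as.character(y), task = "classification")
    list(dataset = ds,
         truth = list(informative = seq_len(n_informative),
                      class_means = mus, effect_size = effect_size,
                      seed = seed))
  })
}

#' Simulate a sparse linear regression dataset
#'
#' @param n_obs Number of samples.
#' @param n_features Total number of features (standard Gaussian).
#' @param n_informative Number of nonzero coefficients (first columns).
#' @param coefficient_scale Coefficient magnitudes are drawn uniformly in
#'   `[0.5, 1.5] * coefficient_scale` with random signs.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param seed Integer seed.
#' @return List with `dataset` (an `ml_dataset`) and `truth` (informative
#'   indices, the full coefficient vector `beta`, `noise_sd`, seed).
#' @export
simulate_regression <- function(n_obs, n_features, n_informative,
                                coefficient_scale = 1, noise_sd = 1,
                                seed = 1L) {
  stopifnot(n_informative <= n_features, noise_sd >= 0)
  with_seed(seed, {
    X <- matrix(stats::rnorm(n_obs * n_features), n_obs, n_features)
    colnames(X) <- paste0("feature_", seq_len(n_features))
    beta <- numeric(n_features)
    if (n_informative > 0L)
      beta[seq_len(n_informative)] <-
        stats::runif(n_informative, 0.5, 1.5) * coefficient_scale *
        sample(c(-1, 1), n_informative, replace = TRUE)
    y <- drop(X %*% beta) + stats::rnorm(n_obs, sd = noise_sd)
    ds <- dataset(X, y, task = "regression")
    list(dataset = ds,
         truth = list(informative = seq_len(n_informative), beta = beta,
                      noise_sd = noise_sd, seed = seed))
  })
}
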