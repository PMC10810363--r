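#' Uniform learner adapters
#'
#' A single fit/predict surface over established implementations:
#' penalized GLMs (glmnet; lasso/ridge/elastic-net), random forests
#' (ranger), linear-kernel SVM (e1071), gradient boosting (xgboost) and
#' k-nearest neighbours (class/caret). Every fitted model exposes
#' per-feature `presence` (0/1) and `sign` (-1/0/+1): for penalized GLMs
#' presence means a nonzero coefficient and sign its sign; learners without
#' coefficients derive presence from their used-feature set (nonzero split
#' importance) with sign fixed at 0, except the linear SVM whose primal
#' weights supply signs in binary problems.
#'
#' @name learners
NULL

.FAMILIES <- c("glm_penalized", "random_forest", "svm_linear", "gbm", "knn")

#' Learner specification
#'
#' @param family One of `"glm_penalized"`, `"random_forest"`,
#'   `"svm_linear"`, `"gbm"`, `"knn"`.
#' @param task `"classification"` or `"regression"`.
#' @param grid Named list of hyperparameter value vectors; the grid of
#'   configurations is their cross product. Recognised names:
#'   glm_penalized: `alpha`, `lambda`; random_forest: `num_trees`, `mtry`;
#'   svm_linear: `cost`; gbm: `nrounds`, `max_depth`, `eta`; knn: `k`.
#' @return A `learner_spec` object.
#' @export
learner_spec <- function(family, task = c("classification", "regression"),
                         grid = list()) {
  family <- match.arg(family, .FAMILIES)
  task <- match.arg(task)
  defaults <- switch(family,
    glm_penalized = list(alpha = 1, lambda = 0.1),
    random_forest = list(num_trees = 500L, mtry = NA),
    svm_linear    = list(cost = 1),
    gbm           = list(nrounds = 100L, max_depth = 3L, eta = 0.3),
    knn           = list(k = 5L))
  for (nm in names(defaults))
    if (is.null(grid[[nm]])) grid[[nm]] <- defaults[[nm]]
  unknown <- setdiff(names(grid), names(defaults))
  if (length(unknown))
    stop("unknown hyperparameter(s) for ", family, ": ",
         paste(unknown, collapse = ", "))
  if (any(lengths(grid) == 0L)) stop("grid values must be non-empty")
  structure(list(family = family, task = task, grid = grid),
            class = "learner_spec")
}

#' Enumerate grid configurations
#' @param spec A `learner_spec`.
#' @return List of named configuration lists (cross product of the grid).
#' @export
grid_configurations <- function(spec) {
  df <- expand.grid(spec$grid, KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

# Declared total order over configurations: indices from simplest to most
# complex. Simpler = larger penalty (glm), larger k (knn), fewer/shallower
# trees (gbm, forest), smaller cost (svm). Ties broken by configuration
# order, making the order total.
#' Order configurations from simplest to most complex
#' @param spec A `learner_spec`.
#' @param configs List of configurations (default: the spec's grid).
#' @return Integer permutation of `seq_along(configs)`.
#' @export
order_by_simplicity <- function(spec, configs = grid_configurations(spec)) {
  key <- switch(spec$family,
    glm_penalized = lapply(configs, function(cf) c(-cf$lambda, -cf$alpha)),
    knn           = lapply(configs, function(cf) -cf$k),
    gbm           = lapply(configs, function(cf)
                           c(cf$nrounds, cf$max_depth, cf$eta)),
    random_forest = lapply(configs, function(cf)
                           c(cf$num_trees, if (is.na(cf$mtry)) 0 else cf$mtry)),
    svm_linear    = lapply(configs, function(cf) cf$cost))
  keym <- do.call(rbind, key)
  do.call(order, c(lapply(seq_len(ncol(keym)), function(j) keym[, j]),
                   list(seq_along(configs))))
}

check_training_input <- function(X, y, task) {
  if (!is.matrix(X)) stop("X_train must be a numeric matrix")
  if (is.null(colnames(X))) stop("X_train must have feature names")
  if (anyNA(X)) stop("missing values in the training matrix; impute or ",
                     "filter before fitting")
  if (nrow(X) != length(y)) stop("row count of X and length of y differ")
  if (task == "classification") {
    y <- as.factor(y)
    if (nlevels(droplevels(y)) < 2L)
      stop("single-class training response")
    droplevels(y)
  } else as.numeric(y)
}

#' Fit a learner at a fixed configuration
#'
#' Trains the underlying implementation on the entire training set at the
#' given hyperparameter configuration. Deterministic given `seed`.
#'
#' @param spec A `learner_spec`.
#' @param configuration Named list of hyperparameter values.
#' @param X_train Numeric training matrix with feature names, no missing
#'   values.
#' @param y_train Response (labels for classification, reals for
#'   regression).
#' @param seed Integer seed for learners with internal randomness.
#' @return A `trained_model` with elements `spec`, `configuration`, `fit`,
#'   `feature_names`, `levels` (classification), `presence`, `sign`.
#' @export
fit <- function(spec, configuration, X_train, y_train, seed = 1L) {
  stopifnot(inherits(spec, "learner_spec"))
  y <- check_training_input(X_train, y_train, spec$task)
  cf <- configuration
  feats <- colnames(X_train)
  p <- length(feats)
  presence <- stats::setNames(rep(0L, p), feats)
  sgn <- stats::setNames(rep(0L, p), feats)
  lv <- if (spec$task == "classification") levels(y) else NULL

  fitted <- with_seed(seed, switch(spec$family,
    glm_penalized = {
      fam <- if (spec$task == "regression") "gaussian"
             else if (nlevels(y) == 2L) "binomial" else "multinomial"
      glmnet::glmnet(X_train, y, family = fam, alpha = cf$alpha,
                     lambda = cf$lambda)
    },
    random_forest = {
      dat <- data.frame(X_train, check.names = FALSE)
      dat$..y.. <- y
      mtry <- if (is.na(cf$mtry)) NULL else min(cf$mtry, p)
      ranger::ranger(dependent.variable.name = "..y..", data = dat,
                     num.trees = cf$num_trees, mtry = mtry,
                     probability = spec$task == "classification",
                     importance = "impurity", num.threads = 1L,
                     seed = seed)
    },
    svm_linear = e1071::svm(X_train, y, kernel = "linear", cost = cf$cost,
                            scale = FALSE, fitted = FALSE),
    gbm = xgboost::xgboost(X_train, y, nrounds = cf$nrounds,
                           max_depth = cf$max_depth,
                           learning_rate = cf$eta, nthreads = 1L,
                           seed = seed, verbosity = 0),
    knn = list(X = X_train, y = y, k = cf$k)
  ))

  # presence / sign extraction
  if (spec$family == "glm_penalized") {
    co <- glmnet::coef.glmnet(fitted)
    if (is.list(co)) {  # multinomial: one coefficient vector per class
      mats <- lapply(co, function(m) as.matrix(m)[-1L, 1L])
      nz <- Reduce(`|`, lapply(mats, function(v) v != 0))
      presence[feats] <- as.integer(nz[feats])
      # sign ambiguous across classes: fixed at 0 for multinomial fits
    } else {
      v <- as.matrix(co)[-1L, 1L]
      presence[feats] <- as.integer(v[feats] != 0)
      sgn[feats] <- as.integer(sign(v[feats]))
    }
  } else if (spec$family == "random_forest") {
    imp <- fitted$variable.importance
    presence[names(imp)] <- as.integer(imp > 0)
  } else if (spec$family == "svm_linear") {
    w <- drop(crossprod(fitted$coefs, fitted$SV))
    if (!is.null(names(w)) && length(w) == p &&
        (spec$task == "regression" || length(lv) == 2L)) {
      presence[names(w)] <- as.integer(w != 0)
      sgn[names(w)] <- as.integer(sign(w))
      if (spec$task == "classification") {
        # e1071 orients the decision function by order of label appearance,
        # not factor level order; orient signs toward the second (positive)
        # level empirically from the support vectors' decision values
        dv <- drop(fitted$SV %*% w) - fitted$rho
        pr <- stats::predict(fitted, fitted$SV)
        hi <- mean(dv[pr == lv[2L]])
        lo <- mean(dv[pr == lv[1L]])
        if (is.finite(hi) && is.finite(lo) && hi < lo) sgn <- -sgn
      }
    } else {
      presence[] <- 1L
    }
  } else if (spec$family == "gbm") {
    imp <- tryCatch(xgboost::xgb.importance(model = fitted),
                    error = function(e) NULL)
    if (!is.null(imp) && nrow(imp) > 0) presence[imp$Feature] <- 1L
  } else if (spec$family == "knn") {
    presence[] <- 1L  # kNN uses every feature
  }
  presence[sgn != 0L] <- 1L

  structure(list(spec = spec, configuration = cf, fit = fitted,
                 feature_names = feats, levels = lv, seed = seed,
                 presence = presence, sign = sgn),
            class = "trained_model")
}

align_features <- function(object, X) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (is.null(colnames(X)))
    stop("prediction data must carry feature names")
  missing <- setdiff(object$feature_names, colnames(X))
  if (length(missing))
    stop("prediction data lacks model feature(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  X[, object$feature_names, drop = FALSE]
}

#' Predict from a trained model
#'
#' Columns are aligned to the training feature space by name; a missing
#' feature is an error, never a silent positional match.
#'
#' @param object A `trained_model`.
#' @param newdata Matrix (or coercible) with named columns covering the
#'   model's features.
#' @param type `"response"` (labels / reals) or `"score"` (continuous
#'   decision value: probability of the positive class for binary
#'   classification, the prediction itself for regression; `NULL` when the
#'   learner exposes none).
#' @param ... Unused.
#' @return Prediction vector, or `NULL` for an unavailable score.
#' @export
predict.trained_model <- function(object, newdata, type = c("response", "score"),
                                  ...) {
  type <- match.arg(type)
  X <- align_features(object, newdata)
  if (anyNA(X)) stop("missing values in prediction data")
  spec <- object$spec
  task <- spec$task
  lv <- object$levels

  if (task == "regression") {
    pred <- switch(spec$family,
      glm_penalized = drop(stats::predict(object$fit, newx = X)),
      random_forest = stats::predict(object$fit,
        data = data.frame(X, check.names = FALSE),
        num.threads = 1L, seed = object$seed)$predictions,
      svm_linear = unname(stats::predict(object$fit, X)),
      gbm = stats::predict(object$fit, X),
      knn = with_seed(object$seed, {
        fitk <- caret::knnreg(object$fit$X, object$fit$y, k = object$fit$k)
        stats::predict(fitk, data.frame(X, check.names = FALSE))
      })
    )
    return(unname(as.numeric(pred)))
  }

  # classification: obtain class probabilities where the backend offers
  # them, else labels directly
  prob <- NULL
  labels <- NULL
  if (spec$family == "glm_penalized") {
    if (length(lv) == 2L) {
      prob2 <- drop(stats::predict(object$fit, newx = X, type = "response"))
      prob <- cbind(1 - prob2, prob2)
      colnames(prob) <- lv
    } else {
      prob <- stats::predict(object$fit, newx = X, type = "response")[, , 1L]
      colnames(prob) <- object$fit$classnames
      prob <- prob[, lv, drop = FALSE]
    }
  } else if (spec$family == "random_forest") {
    prob <- stats::predict(object$fit,
      data = data.frame(X, check.names = FALSE),
      num.threads = 1L, seed = object$seed)$predictions
    prob <- prob[, lv, drop = FALSE]
  } else if (spec$family == "svm_linear") {
    pr <- stats::predict(object$fit, X, decision.values = TRUE)
    labels <- as.character(pr)
    if (length(lv) == 2L) {
      dv <- drop(attr(pr, "decision.values"))
      # decision value > 0 favours the first level of the pair; convert to
      # a score for the second (positive) level
      prob <- cbind(stats::plogis(dv), stats::plogis(-dv))
      colnames(prob) <- strsplit(colnames(attr(pr, "decision.values")),
                                 "/")[[1L]]
      prob <- prob[, lv, drop = FALSE]
    }
  } else if (spec$family == "gbm") {
    raw <- stats::predict(object$fit, X)
    if (length(lv) == 2L) {
      # probability of the second factor level
      prob <- cbind(1 - raw, raw)
      colnames(prob) <- lv
    } else {
      prob <- raw[, lv, drop = FALSE]
    }
  } else if (spec$family == "knn") {
    pr <- with_seed(object$seed,
      class::knn(object$fit$X, X, object$fit$y, k = object$fit$k,
                 prob = TRUE))
    labels <- as.character(pr)
    winner_frac <- attr(pr, "prob")
    if (length(lv) == 2L) {
      p2 <- ifelse(labels == lv[2L], winner_frac, 1 - winner_frac)
      prob <- cbind(1 - p2, p2)
      colnames(prob) <- lv
    }
  }

  if (type == "score") {
    if (is.null(prob) || length(lv) != 2L) return(NULL)
    return(unname(prob[, lv[2L]]))
  }
  if (is.null(labels)) {
    stopifnot(!is.null(prob))
    labels <- lv[max.col(prob, ties.method = "first")]
  }
  labels
}
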