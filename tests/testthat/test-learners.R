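# Adapter contract battery: every family must satisfy the same
# fit/predict/determinism/presence contract.

families <- c("glm_penalized", "random_forest", "svm_linear", "gbm", "knn")

test_that("every family passes the adapter contract battery", {
  cls <- tiny_classification(seed = 2)
  reg <- tiny_regression(seed = 2)
  for (fam in families) {
    for (task in c("classification", "regression")) {
      ds <- if (task == "classification") cls else reg
      spec <- learner_spec(fam, task)
      cfg <- grid_configurations(spec)[[1]]
      m1 <- fit(spec, cfg, ds$X, ds$y, seed = 31)
      m2 <- fit(spec, cfg, ds$X, ds$y, seed = 31)
      p1 <- predict(m1, ds$X)
      p2 <- predict(m2, ds$X)
      # shapes and determinism under a fixed seed
      expect_length(p1, nrow(ds$X))
      expect_identical(p1, p2, label = paste(fam, task))
      if (task == "regression") expect_type(p1, "double")
      else expect_true(all(p1 %in% levels(ds$y)))
      # presence/sign consistency: sign != 0 implies presence 1
      expect_true(all(m1$presence[m1$sign != 0] == 1L),
                  label = paste(fam, task))
      expect_true(all(m1$presence %in% c(0L, 1L)))
      expect_true(all(m1$sign %in% c(-1L, 0L, 1L)))
      # name-based alignment: permuted columns give identical predictions
      perm <- rev(seq_len(ncol(ds$X)))
      expect_identical(predict(m1, ds$X[, perm]), p1,
                       label = paste(fam, task, "permuted"))
      # missing feature is an error, not a positional match
      expect_error(predict(m1, ds$X[, -1]), "lacks model feature")
    }
  }
})

test_that("penalty extremes control glm feature presence", {
  ds <- tiny_classification(seed = 5)
  spec <- learner_spec("glm_penalized", "classification")
  # total shrinkage: intercept-only model
  m_inf <- fit(spec, list(alpha = 1, lambda = 1e6), ds$X, ds$y)
  expect_true(all(m_inf$presence == 0L))
  expect_true(all(m_inf$sign == 0L))
  # unpenalized fit on full-rank data: every feature present
  reg <- tiny_regression(n = 100, p = 5, seed = 6)
  specr <- learner_spec("glm_penalized", "regression")
  m0 <- fit(specr, list(alpha = 0, lambda = 0), reg$X, reg$y)
  expect_true(all(m0$presence == 1L))
})

test_that("glm presence means exactly a nonzero coefficient", {
  sim <- simulate_regression(150, 30, 3, noise_sd = 0.3, seed = 9)
  spec <- learner_spec("glm_penalized", "regression")
  m <- fit(spec, list(alpha = 1, lambda = 0.2), sim$dataset$X,
           sim$dataset$y)
  co <- as.matrix(glmnet::coef.glmnet(m$fit))[-1, 1]
  expect_identical(unname(m$presence), as.integer(co != 0))
  expect_identical(unname(m$sign), as.integer(sign(co)))
})

test_that("tuned lasso recovers true predictors with correct signs", {
  ok <- 0L
  n_seeds <- 20L
  spec <- learner_spec("glm_penalized", "regression",
                       grid = list(alpha = 1,
                                   lambda = c(0.01, 0.03, 0.1, 0.3)))
  for (s in seq_len(n_seeds)) {
    sim <- simulate_regression(200, 50, 3, coefficient_scale = 1,
                               noise_sd = 0.3, seed = s)
    ds <- sim$dataset
    gs <- grid_search(spec, ds$X, ds$y, inner = inner_scheme(k = 5),
                      metric = "mse", seed = s)
    m <- fit(spec, gs$best_config, ds$X, ds$y, seed = s)
    truth_sign <- sign(sim$truth$beta[1:3])
    if (all(m$presence[1:3] == 1L) &&
        all(m$sign[1:3] == truth_sign)) ok <- ok + 1L
  }
  expect_gte(ok, round(0.9 * n_seeds))
})

test_that("knn with k = 1 reproduces its training labels", {
  ds <- tiny_classification(seed = 3)
  spec <- learner_spec("knn", "classification", grid = list(k = 1L))
  m <- fit(spec, list(k = 1L), ds$X, ds$y)
  expect_identical(predict(m, ds$X), as.character(ds$y))
})

test_that("an unpenalized saturated fit interpolates its training data", {
  reg <- tiny_regression(n = 60, p = 4, seed = 8)
  spec <- learner_spec("glm_penalized", "regression")
  m <- fit(spec, list(alpha = 0, lambda = 0), reg$X, reg$y)
  fitted_vals <- predict(m, reg$X)
  ols <- stats::lm.fit(cbind(1, reg$X), reg$y)$fitted.values
  expect_equal(fitted_vals, unname(ols), tolerance = 1e-3)
})

test_that("fitting rejects invalid inputs", {
  ds <- tiny_classification(seed = 4)
  spec <- learner_spec("glm_penalized", "classification")
  Xna <- ds$X; Xna[1, 1] <- NA
  expect_error(fit(spec, list(alpha = 1, lambda = 0.1), Xna, ds$y),
               "missing values")
  expect_error(fit(spec, list(alpha = 1, lambda = 0.1), ds$X,
                   rep("a", nrow(ds$X))), "single-class")
  expect_error(learner_spec("glm_penalized", "classification",
                            grid = list(gamma = 1)), "unknown hyperparameter")
})

test_that("declared complexity orders match the field conventions", {
  spec <- learner_spec("glm_penalized", "regression",
                       grid = list(alpha = 1, lambda = c(0.01, 1, 0.1)))
  cfgs <- grid_configurations(spec)
  ord <- order_by_simplicity(spec, cfgs)
  expect_equal(vapply(cfgs[ord], `[[`, numeric(1), "lambda"),
               c(1, 0.1, 0.01))  # larger penalty is simpler

  speck <- learner_spec("knn", "classification", grid = list(k = c(1, 9, 5)))
  ordk <- order_by_simplicity(speck)
  expect_equal(vapply(grid_configurations(speck)[ordk], `[[`, numeric(1),
                      "k"), c(9, 5, 1))  # larger k is simpler

  specg <- learner_spec("gbm", "regression",
                        grid = list(nrounds = c(50, 10),
                                    max_depth = c(3, 1), eta = 0.3))
  cfgg <- grid_configurations(specg)
  ordg <- order_by_simplicity(specg, cfgg)
  first <- cfgg[[ordg[1]]]
  expect_equal(c(first$nrounds, first$max_depth), c(10, 1))
})
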