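test_that("the default size grid reproduces its generating rule", {
  expect_equal(default_size_grid(343, 3), c(172, 257, 342))
  expect_equal(default_size_grid(683, 5, max_size = 681),
               c(342, 426, 510, 594, 681))
  expect_equal(default_size_grid(100, 1), 99)
  expect_equal(default_size_grid(10, 3), c(5, 7, 9))
  expect_error(default_size_grid(10, 3, min_size = 9, max_size = 9),
               "exceed")
  expect_error(default_size_grid(10, 2, max_size = 10), "n_obs - 1")
})

test_that("per-size summaries follow the mean/SEM/CI formulas", {
  s <- summarize_size(rep(0.9, 5))
  expect_equal(s$mean, 0.9)
  expect_equal(s$sem, 0)
  expect_equal(c(s$ci_low, s$ci_high), c(0.9, 0.9))

  s <- summarize_size(c(0.8, 0.9), confidence = 0.95)
  expect_equal(s$mean, 0.85)
  expect_equal(s$sd^2, 0.005)
  expect_equal(s$sem, sqrt(0.005 / 2))
  cv <- stats::qt(0.975, df = 1)  # independent quantile for n = 2
  expect_equal(cv, 12.7062, tolerance = 1e-4)
  expect_equal(s$ci_high, 0.85 + cv * s$sem)

  # single score: mean defined, CI flagged undefined
  s1 <- summarize_size(0.7)
  expect_equal(s1$mean, 0.7)
  expect_true(is.na(s1$ci_low))

  # missing scores reduce the effective n
  sm <- summarize_size(c(0.5, NA, 0.7))
  expect_equal(sm$n, 2L)
  expect_equal(sm$n_missing, 1L)
  expect_error(summarize_size(NA_real_), "no scores")

  # brute-force agreement on random vectors
  set.seed(2)
  for (i in 1:100) {
    x <- rnorm(sample(2:30, 1))
    b <- brute_summary(x)
    s <- summarize_size(x)
    expect_equal(s[c("mean", "sd", "sem", "ci_low", "ci_high")], b)
  }
})

test_that("t-based confidence intervals attain nominal coverage", {
  set.seed(33)
  n <- 10; mu <- 0.5; sdv <- 0.1
  covered <- replicate(2000, {
    s <- summarize_size(rnorm(n, mu, sdv))
    s$ci_low <= mu && mu <= s$ci_high
  })
  expect_equal(mean(covered), 0.95, tolerance = 0.015)
})

test_that("a degenerate one-size one-repeat evaluation works", {
  ds <- tiny_classification(n = 60, seed = 21)
  spec <- learner_spec("glm_penalized", "classification",
                       grid = list(alpha = 1, lambda = 0.05))
  ev <- evaluate_method(ds, spec, sizes = 40, n_repeats = 1,
                        metric = "acc", inner = inner_scheme(k = 4),
                        seed = 5)
  expect_length(ev$records, 1)
  sm <- ev$summaries
  expect_equal(nrow(sm), 3)  # one row per slice
  expect_equal(sm$mean[sm$slice == "test"], ev$records[[1]]$test_score)
  expect_identical(ev$best$record_index, 1L)
})

test_that("held-out rows never intersect the rows used for training", {
  ds <- tiny_classification(n = 80, seed = 22)
  spec <- learner_spec("glm_penalized", "classification",
                       grid = list(alpha = 1, lambda = c(0.05, 0.2)))
  ev <- evaluate_method(ds, spec, sizes = c(40, 60), n_repeats = 3,
                        metric = "acc", inner = inner_scheme(k = 4),
                        screening = screening_config(top_k = 5),
                        seed = 7)
  for (r in ev$records) {
    expect_length(intersect(r$train_idx, r$held_out_idx), 0)
    expect_length(r$train_idx, r$size)
    expect_setequal(c(r$train_idx, r$held_out_idx), seq_len(nrow(ds$X)))
  }
  # summaries recompute exactly from the stored records
  for (i in seq_along(ev$sizes)) {
    recs <- Filter(function(r) r$size_index == i, ev$records)
    sc <- vapply(recs, `[[`, numeric(1), "test_score")
    sm <- ev$summaries[ev$summaries$size_index == i &
                         ev$summaries$slice == "test", ]
    expect_equal(sm$mean, mean(sc))
    expect_equal(sm$sem, sd(sc) / sqrt(length(sc)))
  }
})

test_that("best-model selection follows the two-stage CI rule", {
  # hand case: minimized metric, CI uppers 0.30 vs 0.20 -> second size,
  # then its minimum-test-error record
  make_ev <- function(test_scores_by_size, direction = "minimize") {
    sizes <- seq_along(test_scores_by_size) * 10L
    records <- list()
    for (i in seq_along(test_scores_by_size))
      for (j in seq_along(test_scores_by_size[[i]]))
        records[[length(records) + 1]] <- list(
          size_index = i, repeat_id = j, size = sizes[i],
          test_score = test_scores_by_size[[i]][j],
          train_score = 0, full_score = 0, failed = FALSE,
          task_seed = 1L)
    summaries <- do.call(rbind, lapply(seq_along(sizes), function(i) {
      s <- summarize_size(test_scores_by_size[[i]])
      tibble::tibble(size_index = i, size = sizes[i], slice = "test",
                     mean = s$mean, sd = s$sd, sem = s$sem,
                     ci_low = s$ci_low, ci_high = s$ci_high, n = s$n,
                     n_missing = 0L)
    }))
    structure(list(records = records, summaries = summaries,
                   metric = if (direction == "minimize") "mse" else "acc",
                   direction = direction, sizes = sizes),
              class = "method_evaluation")
  }
  ev <- make_ev(list(c(0.30, 0.28, 0.26), c(0.21, 0.20, 0.19)))
  best <- select_best_model(ev)
  expect_equal(best$size_index, 2)
  expect_equal(best$test_score, 0.19)

  # randomized tables against the two-stage brute-force oracle
  set.seed(60)
  for (i in 1:200) {
    n_sizes <- sample(2:5, 1)
    scores <- lapply(seq_len(n_sizes), function(s) round(runif(5), 3))
    direction <- sample(c("minimize", "maximize"), 1)
    ev <- make_ev(scores, direction)
    got <- select_best_model(ev)
    test_sm <- ev$summaries
    bounds <- if (direction == "minimize") test_sm$ci_high else test_sm$ci_low
    want <- brute_best_model(bounds, scores, direction)
    expect_equal(got$size_index, want$size)
    expect_equal(got$test_score, scores[[want$size]][want$record])
  }
})

test_that("identical seeds give identical results for any worker count", {
  ds <- tiny_classification(n = 70, seed = 25)
  spec <- learner_spec("glm_penalized", "classification",
                       grid = list(alpha = 1, lambda = c(0.05, 0.2)))
  run <- function(w) evaluate_method(ds, spec, sizes = c(40, 55),
                                     n_repeats = 3, metric = "acc",
                                     inner = inner_scheme(k = 4), seed = 11,
                                     workers = w)
  e1 <- run(1)
  e4 <- run(4)
  d1 <- file.path(tempfile(), "w1"); d4 <- file.path(tempfile(), "w4")
  write_evaluation(e1, d1)
  write_evaluation(e4, d4)
  for (f in c("evaluation.json", "summaries.csv", "models.csv"))
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d4, f), "raw", 1e7), label = f)
})

test_that("external evaluation rescoring matches internal scores", {
  ds <- tiny_regression(n = 80, seed = 26)
  spec <- learner_spec("glm_penalized", "regression",
                       grid = list(alpha = 1, lambda = c(0.05, 0.2)))
  ev <- evaluate_method(ds, spec, sizes = 50, n_repeats = 2, metric = "mse",
                        inner = inner_scheme(k = 4), seed = 13)
  model <- ev$best_model
  best <- ev$best
  # scoring the model on its own training rows reproduces the record's
  # training score
  tb <- evaluate_model_external(model, ds$X[best$train_idx, ],
                                ds$y[best$train_idx], metrics = "mse")
  expect_equal(tb$value, best$train_score, tolerance = 1e-10)
  # single-observation external set: classification accuracy is 0 or 1
  dsc <- tiny_classification(n = 60, seed = 27)
  specc <- learner_spec("knn", "classification", grid = list(k = 3))
  m <- fit(specc, list(k = 3), dsc$X, dsc$y)
  tb1 <- evaluate_model_external(m, dsc$X[1, , drop = FALSE], dsc$y[1],
                                 metrics = "acc")
  expect_true(tb1$value %in% c(0, 1))
})

test_that("test error deteriorates in expectation under distribution shift", {
  set.seed(71)
  internal <- external <- numeric(20)
  for (s in 1:20) {
    sim <- simulate_regression(150, 10, 3, noise_sd = 0.5, seed = s)
    ds <- sim$dataset
    spec <- learner_spec("glm_penalized", "regression",
                         grid = list(alpha = 1, lambda = 0.15))
    m <- fit(spec, list(alpha = 1, lambda = 0.15), ds$X[1:100, ],
             ds$y[1:100], seed = s)
    internal[s] <- regression_score(ds$y[101:150],
                                    predict(m, ds$X[101:150, ]), "mse")
    # shifted external distribution: features displaced by 2 SD, so the
    # shrinkage bias of the penalized fit is amplified off-support
    Xe <- ds$X[101:150, ] + 2
    ye <- drop(Xe %*% sim$truth$beta) + rnorm(50, sd = 0.5)
    external[s] <- evaluate_model_external(m, Xe, ye, "mse")$value
  }
  expect_gt(mean(external), mean(internal))
})
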