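test_that("moderated t is zero for a feature identical in both groups", {
  set.seed(3)
  X <- matrix(rnorm(40 * 5), 40, 5, dimnames = list(NULL, paste0("f", 1:5)))
  X[, 3] <- rep(seq_len(20), 2)  # same values in both groups
  y <- rep(c("a", "b"), each = 20)
  res <- moderated_t(X, y)
  expect_equal(unname(res$statistic["f3"]), 0)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
})

test_that("prior df 0 reduces to the classical pooled two-sample t", {
  set.seed(8)
  X <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- rep(c("g1", "g2"), c(14, 16))
  res <- moderated_t(X, y, prior_df = 0)
  for (j in 1:4) {
    x1 <- X[y == "g1", j]; x2 <- X[y == "g2", j]
    n1 <- length(x1); n2 <- length(x2)
    sp2 <- ((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2)
    t_classic <- (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    expect_equal(unname(res$statistic[j]), t_classic, tolerance = 1e-12)
  }
  expect_equal(res$df_total, 28)
})

test_that("moderated t agrees with the limma empirical-Bayes oracle", {
  skip_if_not_installed("limma")
  set.seed(42)
  n1 <- 8; n2 <- 10; p <- 200
  X <- matrix(rnorm((n1 + n2) * p, sd = rep(sqrt(rchisq(p, 4) / 4),
                                            each = n1 + n2)),
              n1 + n2, p, dimnames = list(NULL, paste0("f", 1:p)))
  X[, 1:10] <- X[, 1:10] + rep(c(0, 1), c(n1, n2))  # some real effects
  y <- rep(c("a", "b"), c(n1, n2))
  res <- moderated_t(X, y)

  design <- cbind(1, y == "b")
  fit <- limma::eBayes(limma::lmFit(t(X), design))
  # limma tests the b - a contrast; ours is a - b
  expect_equal(unname(res$statistic), -unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(unname(res$p_value), unname(fit$p.value[, 2]),
               tolerance = 1e-6)
  expect_equal(res$d0, fit$df.prior, tolerance = 1e-6)
  expect_equal(res$s02, fit$s2.prior, tolerance = 1e-6)
})

test_that("null moderated-t p-values are approximately uniform", {
  set.seed(19)
  X <- matrix(rnorm(20 * 1000), 20, 1000,
              dimnames = list(NULL, paste0("f", 1:1000)))
  y <- rep(c("a", "b"), each = 10)
  res <- moderated_t(X, y)
  expect_equal(mean(res$p_value < 0.05), 0.05, tolerance = 0.02)
})

test_that("all-constant features make the variance prior inestimable", {
  X <- matrix(1, 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rep(c("g1", "g2"), each = 5)
  expect_error(moderated_t(X, y), "prior inestimable")
  expect_error(moderated_t(X[1:3, ], y[c(1, 2, 6)]), ">= 2 observations")
})

test_that("permutation p-values follow the add-one estimator", {
  set.seed(4)
  # one feature with an enormous effect: observed statistic beats every
  # permutation
  X <- cbind(big = c(rep(0, 10), rep(100, 10)) + rnorm(20, sd = 1e-3))
  y <- rep(c("a", "b"), each = 10)
  res <- permutation_test(X, y, B = 999, seed = 10)
  expect_equal(unname(res$p_value), 1 / 1000)

  # observed statistic at the null centre -> p near 1
  X0 <- cbind(null = rep(c(1, 2), 10))
  y0 <- rep(c("a", "b"), each = 10)
  res0 <- permutation_test(X0, y0, B = 499, seed = 10)
  expect_gt(unname(res0$p_value), 0.9)

  expect_error(permutation_test(X, rep("a", 20)), "constant response")
})

test_that("exhaustive permutation equals full enumeration on 6 samples", {
  set.seed(6)
  X <- matrix(rnorm(6 * 3), 6, 3, dimnames = list(NULL, c("u", "v", "w")))
  X[, 1] <- X[, 1] + c(0, 0, 0, 3, 3, 3)
  y <- rep(c("a", "b"), each = 3)
  res <- permutation_test(X, y, exhaustive = TRUE)

  # independent oracle: enumerate all choose(6, 3) = 20 assignments
  combs <- combn(6, 3)
  expect_equal(ncol(combs), 20)
  stat <- function(lab) colMeans(X[lab == "a", , drop = FALSE]) -
    colMeans(X[lab == "b", , drop = FALSE])
  obs <- stat(y)
  hits <- rep(0, 3)
  for (j in seq_len(ncol(combs))) {
    lab <- rep("b", 6); lab[combs[, j]] <- "a"
    hits <- hits + (abs(stat(lab)) >= abs(obs))
  }
  expect_equal(unname(res$p_value), unname(hits / 20))
  # two-sidedness: the complementary assignment always ties |stat|, so the
  # strongest possible exact p is 2/20
  expect_equal(min(res$p_value), 2 / 20)
})

test_that("permutation p-values are valid under the null", {
  set.seed(23)
  X <- matrix(rnorm(12 * 300), 12, 300,
              dimnames = list(NULL, paste0("f", 1:300)))
  y <- rep(c("a", "b"), each = 6)
  res <- permutation_test(X, y, B = 200, seed = 7)
  for (alpha in c(0.01, 0.05, 0.1))
    expect_lte(mean(res$p_value <= alpha), alpha + 0.03)
})

test_that("screen_features applies alpha, top-k and combination rules", {
  set.seed(31)
  sim <- simulate_classification(100, 30, 4, effect_size = 3, seed = 31)
  X <- sim$dataset$X; y <- sim$dataset$y
  # alpha = 1 keeps everything
  sel_all <- screen_features(X, y, screening_config(alpha = 1))
  expect_identical(sel_all, 1:30)
  # top-k cap
  sel4 <- screen_features(X, y, screening_config(alpha = 1, top_k = 4))
  expect_length(sel4, 4)
  expect_setequal(sel4, 1:4)
  # both tests: intersection is a subset of each
  sel_t <- screen_features(X, y, screening_config("moderated_t"))
  sel_b <- screen_features(X, y, screening_config("both", permutations = 200),
                           seed = 1)
  expect_true(all(sel_b %in% sel_t))
})

test_that("screening recovers planted informative features", {
  hits <- 0L
  for (s in 1:100) {
    sim <- simulate_classification(100, 100, 5, effect_size = 2, seed = s)
    sel <- screen_features(sim$dataset$X, sim$dataset$y,
                           screening_config(alpha = 1, top_k = 5))
    if (setequal(sel, 1:5)) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("held-out rows cannot alter the selection (leakage guard)", {
  sim <- simulate_classification(120, 20, 3, effect_size = 2.5, seed = 77)
  X <- sim$dataset$X; y <- sim$dataset$y
  train <- 1:80; held <- 81:120
  base_sel <- screen_features(X[train, ], y[train],
                              screening_config(top_k = 5))
  # plant a feature that encodes the held-out response perfectly but is
  # noise on the training rows; only held-out rows change
  X2 <- X
  X2[held, "feature_10"] <- ifelse(y[held] == levels(y)[2], 10, -10)
  leak_sel <- screen_features(X2[train, ], y[train],
                              screening_config(top_k = 5))
  expect_identical(leak_sel, base_sel)
})
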