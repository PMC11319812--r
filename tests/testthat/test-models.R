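test_that("linear fit recovers exact and degenerate relationships", {
  x <- matrix(seq(-3, 3, length.out = 20), dimnames = list(NULL, "x"))
  fit <- fit_linear(x, 2 * x[, 1] + 1)
  expect_equal(unname(fit$coefficients), c(1, 2), tolerance = 1e-10)
  expect_equal(fit$residual_sd, 0, tolerance = 1e-10)
  fitc <- fit_linear(x, rep(5, 20))
  expect_equal(unname(fitc$coefficients), c(5, 0), tolerance = 1e-10)
})

test_that("linear fit matches the normal-equations solution and flags collinearity", {
  set.seed(10)
  X <- matrix(rnorm(107 * 5), 107, 5, dimnames = list(NULL, paste0("x", 1:5)))
  y <- rnorm(107)
  fit <- fit_linear(X, y)
  Z <- cbind(1, X)
  beta_ne <- solve(t(Z) %*% Z, t(Z) %*% y)  # normal-equations oracle
  expect_equal(unname(fit$coefficients), as.numeric(beta_ne), tolerance = 1e-8)
  Xdup <- cbind(X, x6 = X[, 1])
  expect_error(fit_linear(Xdup, y), "rank-deficient")
})

test_that("mae is the mean absolute deviation, literally", {
  expect_equal(mae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mae(c(0, 2, 4), c(1, 1, 5)), 1)
  expect_equal(mae(3, 0), 3)
  expect_error(mae(1:3, 1:2), "mismatch")
  expect_error(mae(numeric(0), numeric(0)), "empty")
})

test_that("random forest respects its configuration and memorizes at the limit", {
  set.seed(11)
  X <- matrix(rnorm(60 * 31), 60, 31, dimnames = list(NULL, paste0("x", 1:31)))
  y <- rnorm(60)
  fit <- fit_rf(X, y, rf_config(n_trees = 20, seed = 1))
  expect_equal(fit$mtry, ceiling(31 / 3))  # F = ceil(S/3) = 11
  expect_equal(fit$mtry, 11)
  imp <- mdi_importance(fit)
  expect_equal(sum(imp), 1, tolerance = 1e-9)
  # single fully-grown tree trained on all rows reproduces y
  fit1 <- fit_rf(X, y, rf_config(n_trees = 1, mtry = 31, min_node_size = 1,
                                 replace = FALSE, sample_fraction = 1, seed = 2))
  expect_equal(predict(fit1, X), y, tolerance = 1e-12)
})

test_that("the forest beats the linear model on a step-function signal", {
  set.seed(12)
  X <- matrix(rnorm(107 * 5), 107, 5, dimnames = list(NULL, paste0("x", 1:5)))
  y <- 2 * (X[, 1] > 0) + rnorm(107, sd = 0.1)
  rf <- fit_rf(X, y, rf_config(n_trees = 200, seed = 3))
  lmf <- fit_linear(X, y)
  expect_lt(mae(y, predict(rf, X)), mae(y, predict(lmf, X)))
})

test_that("repeated CV covers each observation once per repeat and is deterministic", {
  set.seed(13)
  X <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("x", 1:6)))
  y <- X[, 1] + rnorm(40, sd = 0.3)
  ev <- repeated_cv(X, y, "rf", k = 5, repeats = 2, config = fast_rf(50), seed = 17)
  expect_true(all(colSums(!is.na(ev$predictions)) == 40))
  expect_true(all(!is.na(ev$predictions)))
  ev2 <- repeated_cv(X, y, "rf", k = 5, repeats = 2, config = fast_rf(50), seed = 17)
  expect_identical(ev$predictions, ev2$predictions)
  expect_identical(ev$per_repeat_mae, ev2$per_repeat_mae)
  expect_equal(sum(ev$importance), 1, tolerance = 1e-9)
  expect_true(abs(ev$pearson_r) <= 1)
})

test_that("a target leaked into the features gives near-perfect pooled correlation", {
  rs <- vapply(1:5, function(s) {
    set.seed(s)
    X <- cbind(leak = rnorm(60),
               matrix(rnorm(60 * 3), 60, 3, dimnames = list(NULL, paste0("x", 1:3))))
    ev <- repeated_cv(X, X[, "leak"], "rf", k = 5, repeats = 1,
                      config = fast_rf(200), seed = s)
    ev$pearson_r
  }, numeric(1))
  expect_gt(min(rs), 0.95)
})

test_that("within-fold imputation handles missing cells without global leakage", {
  set.seed(14)
  X <- matrix(rnorm(50 * 4), 50, 4, dimnames = list(NULL, paste0("x", 1:4)))
  y <- X[, 1] + rnorm(50, sd = 0.2)
  Xm <- X; Xm[sample(200, 20)] <- NA
  ev <- repeated_cv(Xm, y, "lm", k = 5, repeats = 2,
                    impute_within_folds = TRUE, seed = 19)
  expect_true(all(is.finite(ev$per_repeat_mae)))
  expect_error(repeated_cv(Xm, y, "lm", k = 5, repeats = 2, seed = 19),
               "impute")
})

test_that("boruta-in-CV reports selection frequencies and uses selected features", {
  set.seed(15)
  X <- cbind(signal = rnorm(80),
             matrix(rnorm(80 * 7), 80, 7, dimnames = list(NULL, paste0("n", 1:7))))
  y <- 1.5 * X[, "signal"] + rnorm(80, sd = 0.3)
  ev <- repeated_cv(X, y, "rf", k = 4, repeats = 1, use_boruta = TRUE,
                    config = fast_rf(100),
                    boruta_args = list(max_runs = 12, rf_params = fast_rf(60)),
                    seed = 23)
  expect_gte(ev$selection_freq[["signal"]], 0.75)
  expect_gt(ev$importance[["signal"]], max(ev$importance[paste0("n", 1:7)]))
})
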