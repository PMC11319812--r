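test_that("shadow columns are permutations with broken association", {
  set.seed(1)
  X <- cbind(a = rnorm(107), b = runif(107), c = rep(2, 107))
  aug <- make_shadows(X, seed = 4)
  expect_equal(dim(aug), c(107, 6))
  expect_identical(aug[, 1:3], X)
  for (j in 1:3) expect_equal(sort(aug[, j + 3]), sort(X[, j]))
  expect_true(all(aug[, "shadow_c"] == 2))
  # |cor(shadow, original)| consistent with the permutation null
  null_q <- quantile(replicate(500, abs(cor(X[, 1], sample(X[, 1])))), 0.999)
  expect_lt(abs(cor(aug[, "a"], aug[, "shadow_a"])), null_q)
  expect_identical(make_shadows(X, seed = 4), aug)
})

test_that("Z-scores single out an informative feature and zero constant ones", {
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    X <- cbind(signal = rnorm(107), matrix(rnorm(107 * 5), 107, 5,
               dimnames = list(NULL, paste0("n", 1:5))))
    y <- X[, "signal"]
    z <- importance_zscores(X, y, rf_params = rf_config(n_trees = 200, min_node_size = 5),
                            seed = s)
    names(which.max(z))
  }, character(1))
  expect_true(all(hits == "signal"))
})

test_that("constant features get Z = 0 and tiny forests are rejected", {
  set.seed(2)
  X <- cbind(x = rnorm(80), const = rep(1, 80))
  y <- X[, "x"] + rnorm(80, sd = 0.1)
  z <- importance_zscores(X, y, seed = 3)
  expect_equal(unname(z["const"]), 0)
  expect_error(importance_zscores(X, y, rf_params = rf_config(n_trees = 1)),
               "2 trees")
})

test_that("shadow and real Z-scores are exchangeable under a pure-noise target", {
  pvals <- vapply(1:8, function(s) {
    set.seed(1000 + s)
    X <- matrix(rnorm(107 * 8), 107, 8, dimnames = list(NULL, paste0("v", 1:8)))
    y <- rnorm(107)
    z <- importance_zscores(make_shadows(X), y,
                            rf_params = rf_config(n_trees = 100, min_node_size = 5))
    suppressWarnings(wilcox.test(z[1:8], z[9:16])$p.value)
  }, numeric(1))
  expect_gt(min(p.adjust(pvals, "bonferroni")), 0.01)
})

test_that("boruta confirms an informative feature and is reproducible", {
  set.seed(5)
  X <- cbind(signal = rnorm(107),
             matrix(rnorm(107 * 10), 107, 10, dimnames = list(NULL, paste0("n", 1:10))))
  y <- X[, "signal"] + rnorm(107, sd = 0.2)
  bd <- boruta_run(X, y, max_runs = 30, seed = 7, rf_params = fast_rf())
  expect_true("signal" %in% confirmed_features(bd))
  expect_true(all(bd$table$hits <= bd$table$runs))
  bd2 <- boruta_run(X, y, max_runs = 30, seed = 7, rf_params = fast_rf())
  expect_identical(bd$table, bd2$table)
  expect_identical(bd$z_history, bd2$z_history)
})

test_that("binomial decision boundaries behave as expected at M = 100", {
  # 100/100 hits -> confirmed at any sensible alpha; 50/100 -> tentative
  p_all <- 2 * pbinom(99, 100, 0.5, lower.tail = FALSE)
  expect_lt(p_all, 1e-25)
  p_half <- 2 * min(pbinom(49, 100, 0.5, lower.tail = FALSE), pbinom(50, 100, 0.5))
  expect_gt(p_half, 0.5)
})

test_that("hits grow with planted effect size (in expectation over seeds)", {
  mean_hits <- vapply(c(0.3, 0.9), function(beta) {
    h <- vapply(1:20, function(s) {
      set.seed(2000 + s)
      X <- cbind(f = rnorm(90),
                 matrix(rnorm(90 * 5), 90, 5, dimnames = list(NULL, paste0("n", 1:5))))
      y <- beta * X[, "f"] + rnorm(90)
      bd <- boruta_run(X, y, max_runs = 12, seed = s,
                       rf_params = rf_config(n_trees = 60, min_node_size = 5))
      bd$table$hits[bd$table$feature == "f"] / bd$table$runs[bd$table$feature == "f"]
    }, numeric(1))
    mean(h)
  }, numeric(1))
  expect_gte(mean_hits[2], mean_hits[1])
})

test_that("duplicate noise columns do not get confirmed above the nominal level", {
  confirmed <- unlist(lapply(1:10, function(s) {
    set.seed(3000 + s)
    noise <- rnorm(80)
    X <- cbind(signal = rnorm(80), n1 = noise, n2 = noise, n3 = rnorm(80))
    y <- X[, "signal"] + rnorm(80, sd = 0.3)
    bd <- boruta_run(X, y, max_runs = 15, seed = s,
                     rf_params = rf_config(n_trees = 60, min_node_size = 5))
    intersect(confirmed_features(bd), c("n1", "n2", "n3"))
  }))
  expect_lte(length(confirmed), 2)  # ~alpha-level false positives over 30 trials
})
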