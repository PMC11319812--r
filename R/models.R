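#' Ordinary least-squares linear model
#'
#' Fits `y = b0 + b1 x1 + ... + bn xn + eta` by least squares and errors
#' on rank-deficient design matrices (e.g. duplicate columns).
#'
#' @param X feature matrix with `nrow(X) > ncol(X)`.
#' @param y numeric target.
#' @return object of class `linear_fit` with `coefficients` (intercept
#'   first) and `residual_sd`.
#' @export
fit_linear <- function(X, y) {
  .assert_matrix_xy(X, y)
  if (nrow(X) <= ncol(X)) stop("need more rows than features for least squares")
  Z <- cbind(`(Intercept)` = 1, X)
  dec <- qr(Z)
  if (dec$rank < ncol(Z)) stop("rank-deficient design matrix (collinear or duplicate columns)")
  beta <- qr.coef(dec, y)
  res <- y - as.numeric(Z %*% beta)
  structure(list(coefficients = beta,
                 residual_sd = sqrt(sum(res^2) / max(1, nrow(X) - ncol(Z))),
                 feature_names = colnames(X)),
            class = "linear_fit")
}

#' @export
predict.linear_fit <- function(object, newdata, ...) {
  Z <- cbind(1, newdata[, object$feature_names, drop = FALSE])
  as.numeric(Z %*% object$coefficients)
}

#' Mean absolute error
#'
#' `(1/n) * sum(|A_i - P_i|)` between actual and predicted values.
#'
#' @param actual,predicted numeric vectors of equal positive length.
#' @return nonnegative scalar.
#' @export
mae <- function(actual, predicted) {
  if (length(actual) == 0) stop("empty vectors")
  if (length(actual) != length(predicted)) stop("length mismatch")
  mean(abs(actual - predicted))
}

#' Repeated k-fold cross-validation of SMR regressions
#'
#' For each of `repeats` repetitions, draws a fresh random `k`-fold
#' partition, fits the model on each training fold (optionally after
#' Boruta selection on that fold only) and predicts the held-out fold, so
#' every observation is predicted exactly once per repeat. Reports the
#' per-repeat MAE (mean over folds), the Pearson correlation between
#' pooled out-of-fold predictions and actuals with its two-sided p-value,
#' the mean impurity importance over all fits (features not selected in a
#' fit score 0 there) and, with Boruta, each feature's confirmation
#' frequency.
#'
#' @param X feature matrix.
#' @param y numeric target.
#' @param model `"rf"` or `"lm"`.
#' @param k number of folds (default 5).
#' @param repeats number of repetitions (default 100).
#' @param use_boruta run [boruta_run()] inside each training fold and fit
#'   on the confirmed features (all features if none are confirmed).
#' @param config [rf_config()] for the prediction forest.
#' @param boruta_args list of arguments forwarded to [boruta_run()]
#'   (`max_runs`, `alpha`, `rf_params`).
#' @param impute_within_folds if `TRUE`, `X` may contain missing values
#'   and each fold imputes them with the training-fold column means,
#'   avoiding the information leak of global pre-imputation. Defaults to
#'   `FALSE`: the panel is imputed once, globally, before splitting, which
#'   is the behaviour of the original analysis.
#' @param seed master seed; folds, forests and selections all derive from
#'   it.
#' @return object of class `cv_evaluation`.
#' @export
repeated_cv <- function(X, y, model = c("rf", "lm"), k = 5, repeats = 100,
                        use_boruta = FALSE, config = rf_config(),
                        boruta_args = list(), impute_within_folds = FALSE,
                        seed = 1L) {
  model <- match.arg(model)
  if (impute_within_folds) {
    if (!is.matrix(X) || nrow(X) != length(y) || anyNA(y))
      stop("X must be a matrix aligned with a complete y")
  } else {
    .assert_matrix_xy(X, y)
  }
  n <- nrow(X)
  if (n < k) stop("fewer observations than folds")
  features <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
  colnames(X) <- features
  .with_seed(.subseed(seed, "repeated_cv"), {
    preds <- matrix(NA_real_, n, repeats, dimnames = list(rownames(X), NULL))
    per_repeat_mae <- numeric(repeats)
    imp_sum <- setNames(numeric(ncol(X)), features)
    sel_count <- setNames(numeric(ncol(X)), features)
    n_fits <- 0L
    for (r in seq_len(repeats)) {
      fold <- sample(rep(seq_len(k), length.out = n))
      fold_mae <- numeric(k)
      for (f in seq_len(k)) {
        tr <- which(fold != f); te <- which(fold == f)
        if (length(tr) < 2) stop("training fold with fewer than 2 rows")
        Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
        if (impute_within_folds && anyNA(X)) {
          for (j in which(colSums(is.na(X)) > 0)) {
            mu <- mean(Xtr[, j], na.rm = TRUE)
            if (is.nan(mu)) stop("column ", features[j], " fully missing in a training fold")
            Xtr[is.na(Xtr[, j]), j] <- mu
            Xte[is.na(Xte[, j]), j] <- mu
          }
        }
        sel <- features
        if (use_boruta) {
          bd <- do.call(boruta_run,
                        c(list(X = Xtr, y = y[tr], seed = .draw_seed()),
                          boruta_args))
          conf <- confirmed_features(bd)
          if (length(conf) > 0) sel <- conf
          sel_count[conf] <- sel_count[conf] + 1
        }
        if (model == "rf") {
          cfg <- config; cfg$seed <- .draw_seed()
          fit <- fit_rf(Xtr[, sel, drop = FALSE], y[tr], cfg)
          imp <- mdi_importance(fit)
          imp_sum[names(imp)] <- imp_sum[names(imp)] + imp
        } else {
          fit <- fit_linear(Xtr[, sel, drop = FALSE], y[tr])
        }
        n_fits <- n_fits + 1L
        pr <- predict(fit, Xte)
        preds[te, r] <- pr
        fold_mae[f] <- mae(y[te], pr)
      }
      per_repeat_mae[r] <- mean(fold_mae)
    }
    ct <- cor.test(as.vector(preds), rep(y, repeats))
    structure(list(model = model, k = k, repeats = repeats,
                   use_boruta = use_boruta,
                   per_repeat_mae = per_repeat_mae,
                   mae_mean = mean(per_repeat_mae),
                   mae_sd = sd(per_repeat_mae),
                   predictions = preds, actuals = y,
                   pearson_r = unname(ct$estimate), p_value = ct$p.value,
                   importance = if (model == "rf") imp_sum / n_fits else NULL,
                   selection_freq = if (use_boruta) sel_count / n_fits else NULL),
              class = "cv_evaluation")
  })
}

#' @export
print.cv_evaluation <- function(x, ...) {
  cat(sprintf("cv_evaluation: %s%s, %d-fold CV x %d repeats\n",
              toupper(x$model), if (x$use_boruta) " + Boruta" else "",
              x$k, x$repeats))
  cat(sprintf("  MAE %.4f +/- %.4f;  pooled Pearson r = %.3f (p = %.2g)\n",
              x$mae_mean, x$mae_sd, x$pearson_r, x$p_value))
  invisible(x)
}
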