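#' Exact Shapley values by subset enumeration
#'
#' For every feature `j`, sums the weighted marginal contributions
#' `w(F) * [f_x(F + j) - f_x(F)]` over all subsets `F` of the remaining
#' features, with `w(F) = |F|! (|S|-|F|-1)! / |S|!`. The value function
#' `f_x(F)` is the interventional expectation: the mean model prediction
#' over the background rows with the features in `F` fixed to `x`'s
#' values. Enumeration is limited to 15 features; use [shap_fast()] for
#' forests beyond that.
#'
#' @param predict_fun function taking a feature matrix and returning
#'   numeric predictions.
#' @param x single explained sample (named numeric vector or single-row
#'   matrix).
#' @param background reference matrix with the same columns.
#' @return Shapley vector, one value per feature, with attributes `base`
#'   (`f_x` of the empty subset) and `prediction` (`f_x` of the full set).
#' @export
shap_exact <- function(predict_fun, x, background) {
  x <- if (is.matrix(x)) x[1, ] else x
  if (!is.matrix(background) || nrow(background) == 0)
    stop("background must be a non-empty matrix")
  p <- ncol(background)
  if (length(x) != p) stop("x and background widths differ")
  if (p > 15) stop("more than 15 features; enumeration infeasible, use shap_fast")
  n_mask <- 2^p
  fvals <- numeric(n_mask)
  bits <- function(mask) which(bitwAnd(mask, bitwShiftL(1L, 0:(p - 1))) != 0L)
  for (mask in 0:(n_mask - 1)) {
    B <- background
    if (mask > 0) for (j in bits(mask)) B[, j] <- x[j]
    fvals[mask + 1] <- mean(predict_fun(B))
  }
  w <- factorial(0:(p - 1)) * factorial(p - (0:(p - 1)) - 1) / factorial(p)
  phi <- numeric(p)
  for (mask in 0:(n_mask - 1)) {
    in_mask <- bits(mask)
    sz <- length(in_mask)
    for (j in setdiff(seq_len(p), in_mask)) {
      phi[j] <- phi[j] + w[sz + 1] *
        (fvals[bitwOr(mask, bitwShiftL(1L, j - 1L)) + 1] - fvals[mask + 1])
    }
  }
  names(phi) <- colnames(background)
  attr(phi, "base") <- fvals[1]
  attr(phi, "prediction") <- fvals[n_mask]
  phi
}

#' Fast interventional Shapley values for a random forest
#'
#' Polynomial-time tree-ensemble Shapley values under the same
#' interventional (background-conditioned) value function as
#' [shap_exact()]: each tree is traversed once per explained/background
#' row pair and each leaf's value is attributed with exact Shapley
#' weights to the features that decide whether the hybrid sample reaches
#' it.
#'
#' @param fit an `rf_fit` from [fit_rf()].
#' @param X explained samples (matrix, columns matching the fit).
#' @param background reference matrix.
#' @return matrix of Shapley values (samples x features) with attribute
#'   `base`, the mean forest prediction over the background. Rows satisfy
#'   `sum(shap) + base = prediction`.
#' @export
shap_fast <- function(fit, X, background) {
  stopifnot(inherits(fit, "rf_fit"))
  X <- as.matrix(X[, fit$feature_names, drop = FALSE])
  background <- as.matrix(background[, fit$feature_names, drop = FALSE])
  if (nrow(background) == 0) stop("background must be non-empty")
  S <- cpp_forest_shap(.extract_forest(fit), X, background)
  dimnames(S) <- list(rownames(X), fit$feature_names)
  attr(S, "base") <- mean(predict(fit, background))
  S
}

#' Shapley attribution under repeated cross-validation
#'
#' For each repeat and fold, fits a forest on the training fold
#' (optionally restricted to Boruta-confirmed features), computes
#' interventional Shapley values for the held-out fold with the training
#' fold as background (subsampled to `background_cap` rows), and averages
#' each province's values over the repeats.
#'
#' @param X feature matrix.
#' @param y numeric target.
#' @param config [rf_config()] for the forests.
#' @param k folds (default 5).
#' @param repeats repetitions (default 100).
#' @param use_boruta select features per training fold with
#'   [boruta_run()]; unselected features get Shapley value 0 in that fit.
#' @param boruta_args arguments forwarded to [boruta_run()].
#' @param background_cap maximum background rows (default 100).
#' @param seed master seed.
#' @return object of class `shap_report`.
#' @export
shap_cv <- function(X, y, config = rf_config(), k = 5, repeats = 100,
                    use_boruta = FALSE, boruta_args = list(),
                    background_cap = 100, seed = 1L) {
  .assert_matrix_xy(X, y)
  n <- nrow(X); p <- ncol(X)
  features <- colnames(X) %||% paste0("V", seq_len(p))
  colnames(X) <- features
  .with_seed(.subseed(seed, "shap_cv"), {
    acc <- matrix(0, n, p, dimnames = list(rownames(X), features))
    base_acc <- 0
    for (r in seq_len(repeats)) {
      fold <- sample(rep(seq_len(k), length.out = n))
      for (f in seq_len(k)) {
        tr <- which(fold != f); te <- which(fold == f)
        sel <- features
        if (use_boruta) {
          bd <- do.call(boruta_run,
                        c(list(X = X[tr, , drop = FALSE], y = y[tr],
                               seed = .draw_seed()), boruta_args))
          conf <- confirmed_features(bd)
          if (length(conf) > 0) sel <- conf
        }
        cfg <- config; cfg$seed <- .draw_seed()
        fit <- fit_rf(X[tr, sel, drop = FALSE], y[tr], cfg)
        bg <- tr
        if (length(bg) > background_cap) bg <- sort(sample(bg, background_cap))
        S <- shap_fast(fit, X[te, sel, drop = FALSE], X[bg, sel, drop = FALSE])
        acc[te, sel] <- acc[te, sel] + S
        base_acc <- base_acc + attr(S, "base") * length(te) / n
      }
    }
    values <- acc / repeats
    rank_tab <- data.frame(feature = features,
                           mean_abs_shap = colMeans(abs(values)))
    rank_tab <- rank_tab[order(-rank_tab$mean_abs_shap), ]
    rownames(rank_tab) <- NULL
    structure(list(values = values, base = base_acc / repeats,
                   ranking = rank_tab, k = k, repeats = repeats),
              class = "shap_report")
  })
}

#' Average per-repeat Shapley matrices into a report
#'
#' @param shap_list list of equally sized province x feature matrices,
#'   one per repeat.
#' @return object of class `shap_report` whose `values` is the
#'   element-wise mean and whose ranking orders features by mean absolute
#'   Shapley value.
#' @export
aggregate_shap <- function(shap_list) {
  if (length(shap_list) == 0) stop("empty list")
  dims <- lapply(shap_list, dim)
  if (!all(vapply(dims, identical, TRUE, dims[[1]])))
    stop("Shapley matrices differ in shape")
  values <- Reduce(`+`, shap_list) / length(shap_list)
  rank_tab <- data.frame(feature = colnames(values) %||% paste0("V", seq_len(ncol(values))),
                         mean_abs_shap = colMeans(abs(values)))
  rank_tab <- rank_tab[order(-rank_tab$mean_abs_shap), ]
  rownames(rank_tab) <- NULL
  structure(list(values = values, base = NA_real_, ranking = rank_tab,
                 k = NA_integer_, repeats = length(shap_list)),
            class = "shap_report")
}

#' @export
print.shap_report <- function(x, ...) {
  cat(sprintf("shap_report: %d provinces x %d features over %d repeats\n",
              nrow(x$values), ncol(x$values), x$repeats))
  cat("  top features by mean |SHAP|:\n")
  top <- utils::head(x$ranking, 5)
  for (i in seq_len(nrow(top)))
    cat(sprintf("    %-28s %.5f\n", top$feature[i], top$mean_abs_shap[i]))
  invisible(x)
}
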