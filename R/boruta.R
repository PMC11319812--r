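#' Append shadow features
#'
#' For each column of `X`, adds an independent row permutation of that
#' column named `shadow_<name>`. Shadows keep every marginal distribution
#' but break any association with the target.
#'
#' @param X numeric feature matrix.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return matrix with `2 * ncol(X)` columns, originals first.
#' @export
make_shadows <- function(X, seed = NULL) {
  if (!is.matrix(X) || ncol(X) < 1) stop("X must be a matrix with at least one column")
  permute <- function() {
    sh <- apply(X, 2, function(col) col[sample.int(length(col))])
    colnames(sh) <- paste0("shadow_", colnames(X))
    cbind(X, sh)
  }
  if (is.null(seed)) permute() else .with_seed(seed, permute())
}

#' Permutation-importance Z-scores
#'
#' Fits a random forest and computes, per tree, the out-of-bag increase in
#' squared error after permuting each feature once (mean decrease
#' accuracy). The Z-score of a feature is the mean per-tree accuracy loss
#' divided by its standard deviation across trees; a zero standard
#' deviation (e.g. a constant or never-used feature) yields Z = 0 by
#' convention.
#'
#' @param X_aug feature matrix, typically [make_shadows()] output.
#' @param y numeric target.
#' @param rf_params an [rf_config()] for the importance forest.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return named Z-score vector, one per column of `X_aug`.
#' @export
importance_zscores <- function(X_aug, y, rf_params = rf_config(n_trees = 200, min_node_size = 5),
                               seed = NULL) {
  if (rf_params$n_trees < 2)
    stop("at least 2 trees are required for a Z-score (sd over trees)")
  run <- function() {
    rf_params$seed <- .draw_seed()
    fit <- fit_rf(X_aug, y, rf_params)
    loss <- cpp_forest_mda(.extract_forest(fit), X_aug, as.numeric(y),
                           .inbag_matrix(fit), .draw_seed())
    mu <- colMeans(loss)
    s <- apply(loss, 2, sd)
    z <- ifelse(s > 0, mu / s, 0)
    names(z) <- colnames(X_aug)
    z
  }
  if (is.null(seed)) run() else .with_seed(.subseed(seed, "zscores"), run())
}

#' Boruta all-relevant feature selection
#'
#' Repeatedly (up to `max_runs` times) regenerates shadow features, refits
#' the importance forest, and records a hit for every feature whose
#' Z-score exceeds the maximum shadow Z-score (MZSA) of that run. After
#' each run, accumulated hits are tested against Binomial(runs, 0.5) with
#' a two-sided test at Bonferroni-corrected `alpha`: features
#' significantly above the 0.5 expectation are confirmed, features
#' significantly below are rejected and dropped from subsequent runs.
#' Features still undecided after `max_runs` stay tentative and are
#' treated as not selected.
#'
#' @param X feature matrix.
#' @param y numeric target.
#' @param max_runs maximum number of shadow runs M (default 100, at
#'   least 10).
#' @param alpha significance level before Bonferroni correction across
#'   the initial number of features (default 0.05).
#' @param rf_params [rf_config()] for the importance forests.
#' @param seed seed for the whole selection.
#' @return object of class `boruta_decision`: a decision table plus the
#'   per-run Z-score history and MZSA sequence.
#' @export
boruta_run <- function(X, y, max_runs = 100, alpha = 0.05,
                       rf_params = rf_config(n_trees = 200, min_node_size = 5),
                       seed = 1L) {
  .assert_matrix_xy(X, y)
  if (max_runs < 10) stop("max_runs must be at least 10")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  p <- ncol(X)
  features <- colnames(X) %||% paste0("V", seq_len(p))
  colnames(X) <- features
  alpha_corr <- alpha / p
  .with_seed(.subseed(seed, "boruta"), {
    status <- setNames(rep("tentative", p), features)
    hits <- setNames(integer(p), features)
    runs_tested <- setNames(integer(p), features)
    z_history <- matrix(NA_real_, p, max_runs, dimnames = list(features, NULL))
    mzsa_seq <- rep(NA_real_, max_runs)
    for (m in seq_len(max_runs)) {
      in_model <- features[status != "rejected"]
      tentative <- features[status == "tentative"]
      if (length(tentative) == 0) break
      X_aug <- make_shadows(X[, in_model, drop = FALSE])
      z <- importance_zscores(X_aug, y, rf_params)
      mzsa <- max(z[grepl("^shadow_", names(z))])
      mzsa_seq[m] <- mzsa
      z_real <- z[in_model]
      z_history[in_model, m] <- z_real
      hit <- z_real > mzsa
      hits[in_model] <- hits[in_model] + hit
      runs_tested[in_model] <- runs_tested[in_model] + 1L
      for (f in tentative) {
        h <- hits[f]; n <- runs_tested[f]
        p_up <- pbinom(h - 1, n, 0.5, lower.tail = FALSE)
        p_down <- pbinom(h, n, 0.5)
        p2 <- min(1, 2 * min(p_up, p_down))
        if (p2 < alpha_corr)
          status[f] <- if (h > n / 2) "confirmed" else "rejected"
      }
    }
    tab <- data.frame(feature = features, status = unname(status),
                      hits = unname(hits), runs = unname(runs_tested),
                      row.names = NULL)
    structure(list(table = tab, z_history = z_history, mzsa = mzsa_seq,
                   alpha = alpha, alpha_corrected = alpha_corr,
                   max_runs = max_runs),
              class = "boruta_decision")
  })
}

#' Features confirmed by a Boruta decision
#' @param decision a `boruta_decision`.
#' @return character vector of confirmed feature names.
#' @export
confirmed_features <- function(decision) {
  stopifnot(inherits(decision, "boruta_decision"))
  decision$table$feature[decision$table$status == "confirmed"]
}

#' @export
print.boruta_decision <- function(x, ...) {
  n <- table(factor(x$table$status, c("confirmed", "tentative", "rejected")))
  cat(sprintf("boruta_decision: %d confirmed, %d tentative, %d rejected (max %d runs, alpha %.3g Bonferroni-corrected to %.3g)\n",
              n["confirmed"], n["tentative"], n["rejected"],
              x$max_runs, x$alpha, x$alpha_corrected))
  invisible(x)
}
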