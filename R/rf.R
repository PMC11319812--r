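#' Random-forest configuration
#'
#' The forest follows the reference configuration for this analysis:
#' 600 trees with `F = ceiling(S/3)` candidate features per split, trees
#' grown to full depth (at least one sample per leaf) on bootstrap samples.
#'
#' @param n_trees ensemble size (default 600).
#' @param mtry candidate features per split; `NULL` means `ceiling(S/3)`
#'   of the matrix actually fitted.
#' @param min_node_size minimal node size to attempt a split (default 1,
#'   i.e. fully grown trees).
#' @param replace bootstrap with replacement (default TRUE).
#' @param sample_fraction fraction of rows drawn per tree (default 1).
#' @param seed RNG seed for the forest; `NULL` draws from the current
#'   stream.
#' @return object of class `rf_config`.
#' @export
rf_config <- function(n_trees = 600, mtry = NULL, min_node_size = 1,
                      replace = TRUE, sample_fraction = 1, seed = NULL) {
  stopifnot(n_trees >= 1, min_node_size >= 1,
            sample_fraction > 0, sample_fraction <= 1)
  if (!is.null(mtry)) stopifnot(mtry >= 1)
  structure(list(n_trees = n_trees, mtry = mtry,
                 min_node_size = min_node_size, replace = replace,
                 sample_fraction = sample_fraction, seed = seed),
            class = "rf_config")
}

#' Fit a random-forest regression
#'
#' Thin wrapper around [ranger::ranger()] holding the configuration, the
#' impurity importances and the flattened tree structures used by the
#' Shapley and permutation-importance routines.
#'
#' @param X numeric feature matrix (no missing values).
#' @param y numeric target.
#' @param config an [rf_config()].
#' @return object of class `rf_fit`.
#' @export
fit_rf <- function(X, y, config = rf_config()) {
  .assert_matrix_xy(X, y)
  stopifnot(inherits(config, "rf_config"))
  mtry <- min(config$mtry %||% ceiling(ncol(X) / 3), ncol(X))
  seed <- config$seed %||% .draw_seed()
  forest <- ranger::ranger(x = X, y = y,
                           num.trees = config$n_trees, mtry = mtry,
                           min.node.size = config$min_node_size,
                           replace = config$replace,
                           sample.fraction = config$sample_fraction,
                           importance = "impurity", keep.inbag = TRUE,
                           seed = seed, num.threads = 1)
  structure(list(forest = forest, config = config, mtry = mtry,
                 feature_names = colnames(X),
                 cache = new.env(parent = emptyenv())),
            class = "rf_fit")
}

#' @export
predict.rf_fit <- function(object, newdata, ...) {
  newdata <- newdata[, object$feature_names, drop = FALSE]
  predict(object$forest, data = newdata, num.threads = 1)$predictions
}

#' Mean-decrease-impurity feature importance
#'
#' Split-gain importances of a fitted forest, normalized to sum to one.
#'
#' @param fit an `rf_fit`.
#' @return named importance vector summing to 1.
#' @export
mdi_importance <- function(fit) {
  stopifnot(inherits(fit, "rf_fit"))
  imp <- fit$forest$variable.importance
  s <- sum(imp)
  if (s <= 0) return(imp * 0)
  imp / s
}

# Flatten the ranger trees into the matrix layout the C++ routines expect.
# Cached on the fit, extraction is the slow part.
.extract_forest <- function(fit) {
  stopifnot(inherits(fit, "rf_fit"))
  if (!is.null(fit$cache$forest)) return(fit$cache$forest)
  out <- lapply(seq_len(fit$forest$num.trees), function(t) {
    ti <- ranger::treeInfo(fit$forest, t)
    term <- ti$terminal
    m <- cbind(ifelse(term, -1, ti$leftChild),
               ifelse(term, -1, ti$rightChild),
               ifelse(term, -1, ti$splitvarID),
               ifelse(term, 0, ti$splitval),
               ifelse(term, ti$prediction, 0))
    storage.mode(m) <- "double"
    m
  })
  fit$cache$forest <- out
  out
}

.inbag_matrix <- function(fit) {
  do.call(cbind, fit$forest$inbag.counts)
}
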