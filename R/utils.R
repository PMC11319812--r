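#' @useDynLib smrnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor cor.test lm coef predict pbinom rnorm runif rpois sd quantile setNames
#' @importFrom utils read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic sub-seed so each operation draws from its own stream while
# everything still flows from one master seed. Kept below 2^31.
.subseed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 16807 + 11) %% 2147483629L)
}

# Evaluate expr under a temporary RNG state.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  expr
}

.draw_seed <- function() sample.int(2147483629L, 1L)

.assert_matrix_xy <- function(X, y) {
  if (!is.matrix(X)) stop("X must be a numeric matrix")
  if (nrow(X) != length(y)) stop("X and y dimensions disagree")
  if (anyNA(X) || anyNA(y)) stop("missing values present; impute first")
}
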