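#' Mean imputation per indicator-year
#'
#' Missing cells are replaced by the mean of the observed values of the
#' same indicator in the same year; observed cells are untouched. The
#' operation is idempotent and leaves column means unchanged.
#'
#' @param panel an `indicator_panel`, possibly with missing cells.
#' @return the imputed panel.
#' @export
impute_mean <- function(panel) {
  stopifnot(inherits(panel, "indicator_panel"))
  vals <- panel$values
  for (t in seq_along(panel$years)) {
    for (j in seq_along(panel$indicators)) {
      col <- vals[, j, t]
      if (!anyNA(col)) next
      obs <- col[!is.na(col)]
      if (length(obs) == 0)
        stop(sprintf("indicator '%s' has no observed value in year %d",
                     panel$indicators[j], panel$years[t]))
      col[is.na(col)] <- mean(obs)
      vals[, j, t] <- col
    }
  }
  panel$values <- vals
  panel
}

#' Assemble a per-year design matrix and SMR target
#'
#' Aligns the imputed panel and the SMR table on province id for one year.
#'
#' @param panel an imputed `indicator_panel`.
#' @param smr_table output of [smr_table()].
#' @param year the year to extract.
#' @return list with `X` (province x indicator matrix), `y` (SMR vector),
#'   `names` (indicator names), `categories`, `provinces`.
#' @export
assemble <- function(panel, smr_table, year) {
  stopifnot(inherits(panel, "indicator_panel"))
  if (!year %in% panel$years) stop("year ", year, " not in panel")
  sub <- smr_table[smr_table$year == year, , drop = FALSE]
  if (nrow(sub) == 0) stop("year ", year, " not in SMR table")
  only_panel <- setdiff(panel$provinces, sub$province_id)
  only_smr <- setdiff(sub$province_id, panel$provinces)
  if (length(only_panel) || length(only_smr))
    stop("provinces present in one input only: ",
         paste(c(only_panel, only_smr), collapse = ", "))
  provinces <- sort(panel$provinces)
  t <- match(year, panel$years)
  X <- panel$values[match(provinces, panel$provinces), , t, drop = TRUE]
  X <- matrix(X, nrow = length(provinces),
              dimnames = list(provinces, panel$indicators))
  if (anyNA(X)) stop("panel still contains missing values; run impute_mean first")
  y <- sub$smr[match(provinces, sub$province_id)]
  list(X = X, y = y, names = panel$indicators,
       categories = panel$categories, provinces = provinces)
}
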