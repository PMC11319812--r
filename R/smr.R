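#' Age-specific reference death rates
#'
#' `R_i = M_i / N_i`: reference deaths per age class divided by reference
#' population per age class.
#'
#' @param deaths nonnegative integer vector `M_i`.
#' @param population positive integer vector `N_i`, same length.
#' @return rate vector in `[0, 1]`.
#' @export
age_specific_rates <- function(deaths, population) {
  if (length(deaths) != length(population))
    stop("deaths and population must have the same length")
  if (any(population <= 0)) stop("reference population must be positive in every age class")
  if (any(deaths < 0)) stop("negative death counts")
  if (any(deaths > population)) stop("deaths exceed population in some age class")
  deaths / population
}

#' Expected deaths by indirect standardization
#'
#' `E_m = sum_i R_i * n_i`: reference age-specific rates weighted by the
#' province's age-class populations.
#'
#' @param rates reference rates in `[0, 1]`.
#' @param population province population per age class.
#' @return expected death count (nonnegative real).
#' @export
expected_deaths <- function(rates, population) {
  if (length(rates) != length(population)) stop("rates and population lengths differ")
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (any(population < 0)) stop("negative population")
  sum(rates * population)
}

#' Standardized mortality ratio
#'
#' `SMR = O_m / E_m`. Values above 1 mean the province's mortality exceeds
#' what the reference population's age-specific rates predict for its age
#' structure.
#'
#' @param observed observed deaths `O_m` (nonnegative).
#' @param expected expected deaths `E_m` (strictly positive).
#' @return the ratio.
#' @export
smr <- function(observed, expected) {
  if (any(expected <= 0))
    stop("expected deaths must be positive; E_m = 0 indicates an empty province")
  if (any(observed < 0)) stop("negative observed deaths")
  observed / expected
}

#' SMR table for every province-year
#'
#' Runs the full indirect standardization on an `age_mortality` object:
#' reference rates from the pooled reference table, expected deaths from
#' each province's age structure, and the observed/expected ratio.
#'
#' @param mortality an `age_mortality` object (see [generate_mortality()]
#'   or [read_mortality_csv()]).
#' @return data.frame with columns `province_id`, `year`, `o_m`, `e_m`,
#'   `smr`.
#' @export
smr_table <- function(mortality) {
  stopifnot(inherits(mortality, "age_mortality"))
  ref <- mortality$reference
  rates <- age_specific_rates(ref$ref_deaths, ref$ref_population)
  e_m <- apply(mortality$population, 1, expected_deaths, rates = rates)
  obs <- mortality$observed
  idx <- match(obs$province_id, rownames(mortality$population))
  if (anyNA(idx)) stop("observed deaths for provinces absent from the population table")
  out <- data.frame(province_id = obs$province_id, year = obs$year,
                    o_m = obs$observed_deaths, e_m = e_m[idx],
                    smr = smr(obs$observed_deaths, e_m[idx]))
  rownames(out) <- NULL
  out
}

#' @rdname smr_table
#' @param table an SMR table.
#' @param path CSV path.
#' @export
write_smr_csv <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname smr_table
#' @export
read_smr_csv <- function(path) read.csv(path)
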