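#' Indicator category vocabulary
#'
#' The five thematic groups used to label provincial indicators: air
#' pollution, soil pollution, urban environment, socio-economic context and
#' mortality from other pathologies (comorbidities).
#' @export
indicator_categories <- c("Air Pollution", "Soil Pollution", "Urban Environment",
                          "Socio-economic", "Other Pathologies")

.category_prefix <- c("Air Pollution" = "air", "Soil Pollution" = "soil",
                      "Urban Environment" = "urban", "Socio-economic" = "socio",
                      "Other Pathologies" = "patho")

.default_indicators <- function() {
  names <- c("air_o3", "air_no2", "air_pm10", "air_pm25", "air_so2",
             "air_benzene", "air_quality_index",
             "soil_heavy_metals", "soil_pesticides", "soil_sealing",
             "soil_contaminated_sites", "soil_nitrates",
             "urban_green_space", "urban_traffic", "urban_density",
             "urban_waste", "urban_noise", "urban_public_transport",
             "socio_income", "socio_education", "socio_unemployment",
             "socio_elderly_share", "socio_gdp", "socio_health_spending",
             "socio_poverty",
             "patho_circulatory", "patho_respiratory", "patho_diabetes",
             "patho_cancer", "patho_kidney", "patho_hypertension")
  cats <- rep(indicator_categories, times = c(7, 5, 6, 7, 6))
  names(cats) <- names
  cats
}

#' Configuration for the synthetic provincial data generator
#'
#' Defines the study conditions emulated by [generate_panel()] and
#' [generate_mortality()]: an indicator panel of `n_provinces` rows by
#' `n_indicators` columns observed over `years`, and age-stratified
#' mortality counts whose log-rate carries planted indicator effects.
#'
#' @param n_provinces number of provinces (default 107).
#' @param n_indicators number of indicators (default 31; the default naming
#'   and category assignment is used when the count is 31, otherwise names
#'   are generated cycling through the five categories).
#' @param years calendar years of observation (default 2015:2019).
#' @param n_age_classes number of five-year age classes (default 18).
#' @param effect_spec named list of planted positive effects on the log
#'   mortality-rate scale; each element is `list(coef =, form =)` with
#'   `form` one of `"linear"`, `"threshold"`, `"quadratic"`. Coefficients
#'   apply to the per-year standardized indicator.
#' @param negative_effect_spec same structure for comorbidity-style
#'   indicators; the absolute coefficient is applied with a negative sign.
#' @param indicator_correlation in `[0, 1)`, the share of indicator variance
#'   carried by a latent regional factor shared within each category.
#' @param noise_sd standard deviation of unexplained log-rate noise.
#' @param panel_jitter_sd year-to-year indicator noise around the stationary
#'   province value.
#' @param missing_rate fraction of panel cells masked by [inject_missing()]
#'   in the full pipeline (MCAR), in `[0, 0.5]`.
#' @param seed master seed; every downstream draw derives from it.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_provinces = 107,
                             n_indicators = 31,
                             years = 2015:2019,
                             n_age_classes = 18,
                             effect_spec = list(
                               air_o3 = list(coef = 0.5, form = "threshold"),
                               air_no2 = list(coef = 0.4, form = "linear")),
                             negative_effect_spec = list(
                               patho_circulatory = list(coef = 0.3, form = "linear")),
                             indicator_correlation = 0.3,
                             noise_sd = 0.1,
                             panel_jitter_sd = 0.05,
                             missing_rate = 0.05,
                             seed = 1L) {
  stopifnot(n_provinces >= 2, n_indicators >= 2, n_age_classes >= 2,
            length(years) >= 1,
            indicator_correlation >= 0, indicator_correlation < 1,
            noise_sd >= 0, panel_jitter_sd >= 0,
            missing_rate >= 0, missing_rate <= 0.5)
  if (n_indicators == 31) {
    cats <- .default_indicators()
  } else {
    cat_idx <- rep_len(seq_along(indicator_categories), n_indicators)
    cats <- indicator_categories[cat_idx]
    names(cats) <- sprintf("ind_%s_%02d", .category_prefix[cats], seq_len(n_indicators))
  }
  forms <- vapply(c(effect_spec, negative_effect_spec), `[[`, "", "form")
  if (!all(forms %in% c("linear", "threshold", "quadratic")))
    stop("effect form must be linear, threshold or quadratic")
  bad <- setdiff(names(c(effect_spec, negative_effect_spec)), names(cats))
  if (length(bad))
    stop("planted effect on unknown indicator(s): ", paste(bad, collapse = ", "))
  structure(list(n_provinces = n_provinces, n_indicators = n_indicators,
                 years = as.integer(years), n_age_classes = n_age_classes,
                 effect_spec = effect_spec,
                 negative_effect_spec = negative_effect_spec,
                 indicator_correlation = indicator_correlation,
                 noise_sd = noise_sd, panel_jitter_sd = panel_jitter_sd,
                 missing_rate = missing_rate,
                 indicators = cats, seed = as.integer(seed)),
            class = "synthetic_config")
}

.new_panel <- function(values, categories, provinces, years) {
  structure(list(provinces = provinces, years = as.integer(years),
                 indicators = names(categories), categories = categories,
                 values = values),
            class = "indicator_panel")
}

#' Generate a synthetic provincial indicator panel
#'
#' Province values are built from one latent regional factor per category:
#' indicator `j` in category `c` for province `p` is
#' `sqrt(rho) * Z[p, c] + sqrt(1 - rho) * eps`, with `rho` the configured
#' `indicator_correlation`, so indicators within a category share
#' correlation `rho` while categories stay independent. Values are
#' stationary across years up to `panel_jitter_sd` jitter.
#'
#' @param config a [synthetic_config()].
#' @return an `indicator_panel`: provinces x indicators x years array with
#'   category labels.
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cats <- config$indicators
  np <- config$n_provinces; ni <- config$n_indicators
  ny <- length(config$years)
  provinces <- sprintf("P%03d", seq_len(np))
  rho <- config$indicator_correlation
  .with_seed(.subseed(config$seed, "panel"), {
    k <- length(indicator_categories)
    Z <- matrix(rnorm(np * k), np, k, dimnames = list(NULL, indicator_categories))
    base <- sqrt(rho) * Z[, cats, drop = FALSE] +
      sqrt(1 - rho) * matrix(rnorm(np * ni), np, ni)
    vals <- array(NA_real_, dim = c(np, ni, ny),
                  dimnames = list(provinces, names(cats), config$years))
    for (t in seq_len(ny))
      vals[, , t] <- base + matrix(rnorm(np * ni, sd = config$panel_jitter_sd), np, ni)
    .new_panel(vals, cats, provinces, config$years)
  })
}

# Planted linear predictor (true log-SMR surface) for one year's values.
.planted_predictor <- function(config, year_values) {
  eta <- numeric(nrow(year_values))
  specs <- c(lapply(config$effect_spec, function(s) {
    s$coef <- abs(s$coef); s
  }), lapply(config$negative_effect_spec, function(s) {
    s$coef <- -abs(s$coef); s
  }))
  for (nm in names(specs)) {
    v <- year_values[, nm]
    z <- (v - mean(v)) / sd(v)
    g <- switch(specs[[nm]]$form,
                linear = z,
                threshold = as.numeric(z > 0.5),
                quadratic = z^2)
    g <- g - mean(g)
    eta <- eta + specs[[nm]]$coef * g
  }
  eta
}

#' Generate age-stratified mortality with planted indicator effects
#'
#' Builds province age pyramids, a pooled reference population with
#' log-linear age-specific death rates, and draws observed deaths per
#' province-year from `Poisson(E_m * exp(eta))`, where `E_m` is the
#' indirectly standardized expected count and `eta` the planted linear
#' predictor plus `N(0, noise_sd)` noise — so the true log-SMR equals the
#' planted predictor in expectation.
#'
#' @param config a [synthetic_config()].
#' @param panel the matching panel from [generate_panel()].
#' @return an `age_mortality` object with components `observed`
#'   (province_id, year, observed_deaths), `population` (province x
#'   age-class matrix), `reference` (age_class, ref_deaths, ref_population)
#'   and `linpred` (true per province-year log-SMR, for diagnostics).
#' @export
generate_mortality <- function(config, panel) {
  stopifnot(inherits(config, "synthetic_config"), inherits(panel, "indicator_panel"))
  planted <- names(c(config$effect_spec, config$negative_effect_spec))
  missing_ind <- setdiff(planted, panel$indicators)
  if (length(missing_ind))
    stop("planted indicator(s) absent from panel: ", paste(missing_ind, collapse = ", "))
  np <- config$n_provinces
  A <- config$n_age_classes
  .with_seed(.subseed(config$seed, "mortality"), {
    # age pyramid: flat through mid-life, tapering over the last 5 classes
    w <- rep(1, A)
    tail_len <- min(5L, A)
    w[(A - tail_len + 1):A] <- seq(0.85, 0.25, length.out = tail_len)
    w <- w / sum(w)
    totals <- round(exp(rnorm(np, log(4.2e5), 0.5)))
    pop <- round(outer(totals, w))
    pop[pop < 1] <- 1
    storage.mode(pop) <- "integer"
    dimnames(pop) <- list(panel$provinces, seq_len(A))
    # reference rates log-linear in age class, scaled to a national crude
    # rate of 4.4 per 10,000 — the order of dementia mortality
    N_ref <- colSums(pop)
    slope <- 0.75
    r0 <- log(4.4e-4) - log(sum(w * exp(slope * seq_len(A))))
    R <- exp(r0 + slope * seq_len(A))
    M_ref <- pmin(as.integer(round(R * N_ref)), N_ref)
    R_real <- M_ref / N_ref
    e_m <- as.numeric(pop %*% R_real)
    obs <- NULL
    linpred <- matrix(0, np, length(config$years),
                      dimnames = list(panel$provinces, config$years))
    for (t in seq_along(config$years)) {
      eta <- .planted_predictor(config, panel$values[, , t])
      if (config$noise_sd > 0) eta <- eta + rnorm(np, sd = config$noise_sd)
      linpred[, t] <- eta
      o <- rpois(np, e_m * exp(eta))
      obs <- rbind(obs, data.frame(province_id = panel$provinces,
                                   year = config$years[t],
                                   observed_deaths = o))
    }
    structure(list(observed = obs, population = pop,
                   reference = data.frame(age_class = seq_len(A),
                                          ref_deaths = unname(M_ref),
                                          ref_population = unname(N_ref)),
                   linpred = linpred),
              class = "age_mortality")
  })
}

#' Mask panel cells completely at random
#'
#' Each province-indicator-year cell is independently set to missing with
#' probability `rate`. Raises an error if an indicator-year column would be
#' left with no observed value.
#'
#' @param panel an `indicator_panel`.
#' @param rate masking probability in `[0, 1)`.
#' @param seed RNG seed.
#' @return the panel with `NA` in masked cells.
#' @export
inject_missing <- function(panel, rate, seed = 1L) {
  stopifnot(inherits(panel, "indicator_panel"), rate >= 0, rate < 1)
  if (rate == 0) return(panel)
  .with_seed(.subseed(seed, "missing"), {
    mask <- array(runif(length(panel$values)) < rate, dim = dim(panel$values))
    vals <- panel$values
    vals[mask] <- NA_real_
    for (t in seq_along(panel$years)) {
      empty <- colSums(!is.na(vals[, , t, drop = FALSE])) == 0
      if (any(empty))
        stop("masking would empty indicator-year column(s): ",
             paste(panel$indicators[empty], panel$years[t], collapse = ", "))
    }
    panel$values <- vals
    panel
  })
}

#' @export
print.indicator_panel <- function(x, ...) {
  cat(sprintf("indicator_panel: %d provinces x %d indicators x %d years (%s)\n",
              length(x$provinces), length(x$indicators), length(x$years),
              paste(range(x$years), collapse = "-")))
  n_miss <- sum(is.na(x$values))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", n_miss,
              100 * n_miss / length(x$values)))
  invisible(x)
}

# ---- CSV interchange ------------------------------------------------------

#' Write / read an indicator panel as CSV
#'
#' Wide layout: `province_id`, `year`, then one column per indicator.
#' Category labels are recovered on read from the indicator name prefix
#' (`air_`, `soil_`, `urban_`, `socio_`, `patho_`, `net_`).
#' @param panel an `indicator_panel`.
#' @param path output file.
#' @export
write_panel_csv <- function(panel, path) {
  rows <- do.call(rbind, lapply(seq_along(panel$years), function(t) {
    data.frame(province_id = panel$provinces, year = panel$years[t],
               panel$values[, , t, drop = TRUE], check.names = FALSE)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

.infer_category <- function(names) {
  pre <- sub("^(ind_)?([a-z]+)_.*$", "\\2", names)
  lookup <- c(air = "Air Pollution", soil = "Soil Pollution",
              urban = "Urban Environment", socio = "Socio-economic",
              patho = "Other Pathologies", net = "Network")
  out <- unname(lookup[pre])
  out[is.na(out)] <- "Socio-economic"
  names(out) <- names
  out
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  stopifnot(all(c("province_id", "year") %in% names(df)))
  ind <- setdiff(names(df), c("province_id", "year"))
  years <- sort(unique(df$year))
  provinces <- sort(unique(df$province_id))
  vals <- array(NA_real_, dim = c(length(provinces), length(ind), length(years)),
                dimnames = list(provinces, ind, years))
  for (t in seq_along(years)) {
    sub <- df[df$year == years[t], , drop = FALSE]
    vals[match(sub$province_id, provinces), , t] <- as.matrix(sub[, ind, drop = FALSE])
  }
  .new_panel(vals, .infer_category(ind), provinces, years)
}

#' Write / read age-stratified mortality as CSV
#'
#' Long layout (`province_id`, `year`, `age_class`, `population`,
#' `observed_deaths`, with the province-year death total repeated on each
#' age row) plus a separate reference table (`age_class`, `ref_deaths`,
#' `ref_population`).
#' @param mortality an `age_mortality` object.
#' @param path,ref_path output files for the province table and the
#'   reference table.
#' @export
write_mortality_csv <- function(mortality, path, ref_path) {
  A <- ncol(mortality$population)
  long <- merge(mortality$observed,
                data.frame(province_id = rep(rownames(mortality$population), A),
                           age_class = rep(seq_len(A), each = nrow(mortality$population)),
                           population = as.vector(mortality$population)),
                by = "province_id")
  long <- long[order(long$province_id, long$year, long$age_class),
               c("province_id", "year", "age_class", "population", "observed_deaths")]
  write.csv(long, path, row.names = FALSE)
  write.csv(mortality$reference, ref_path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mortality_csv
#' @export
read_mortality_csv <- function(path, ref_path) {
  long <- read.csv(path)
  ref <- read.csv(ref_path)
  provinces <- sort(unique(long$province_id))
  ages <- sort(unique(long$age_class))
  one_year <- long[long$year == long$year[1], ]
  one_year <- one_year[order(one_year$province_id, one_year$age_class), ]
  pop <- matrix(one_year$population, nrow = length(provinces), byrow = TRUE,
                dimnames = list(provinces, ages))
  storage.mode(pop) <- "integer"
  obs <- unique(long[, c("province_id", "year", "observed_deaths")])
  obs <- obs[order(obs$year, obs$province_id), ]
  rownames(obs) <- NULL
  structure(list(observed = obs, population = pop, reference = ref,
                 linpred = NULL),
            class = "age_mortality")
}
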