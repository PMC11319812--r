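#' Pipeline configuration
#'
#' Bundles the synthetic-data configuration with the modelling choices of
#' the full per-year analysis run by [run_pipeline()].
#'
#' @param synth a [synthetic_config()]; its `seed` is overridden by
#'   `seed`.
#' @param k CV folds.
#' @param repeats CV repetitions for the model comparison.
#' @param rf [rf_config()] for the prediction forests.
#' @param boruta_args arguments for [boruta_run()] inside the CV.
#' @param network run the similarity-network robustness variant.
#' @param shap_repeats CV repetitions for the Shapley report (`0` skips
#'   it).
#' @param map_indicators indicator names averaged with the SMR layer in
#'   the combined min-max map.
#' @param seed master seed for the whole run.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synthetic_config(), k = 5, repeats = 100,
                            rf = rf_config(), boruta_args = list(),
                            network = TRUE, shap_repeats = 10,
                            map_indicators = c("air_o3", "air_no2"),
                            seed = 1L) {
  stopifnot(inherits(synth, "synthetic_config"), k >= 2, repeats >= 1)
  synth$seed <- as.integer(seed)
  structure(list(synth = synth, k = k, repeats = repeats, rf = rf,
                 boruta_args = boruta_args, network = network,
                 shap_repeats = shap_repeats,
                 map_indicators = map_indicators, seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Min-max-normalized average of province-level layers
#'
#' Each layer is scaled to `[0, 1]` by min-max normalization and the
#' layers are averaged element-wise; a constant layer carries no spatial
#' information and is mapped to zeros with a warning.
#'
#' @param layers province x layer matrix, or a list/data.frame of aligned
#'   province vectors.
#' @return named vector of combined values in `[0, 1]`.
#' @export
normalized_average_map <- function(layers) {
  if (is.list(layers) && !is.data.frame(layers)) {
    ids <- lapply(layers, names)
    if (length(unique(ids)) > 1) stop("layers have misaligned province ids")
    layers <- do.call(cbind, layers)
  }
  layers <- as.matrix(layers)
  if (ncol(layers) < 1) stop("need at least one layer")
  norm <- apply(layers, 2, function(v) {
    rng <- range(v)
    if (diff(rng) == 0) {
      warning("constant layer mapped to zeros")
      return(rep(0, length(v)))
    }
    (v - rng[1]) / diff(rng)
  })
  out <- rowMeans(norm)
  names(out) <- rownames(layers)
  out
}

#' Feature-importance table across years
#'
#' Mean impurity importance per feature and year from the CV evaluations;
#' when Boruta selection frequencies are available, features confirmed in
#' at most half of the fits are marked absent (`NA`) for that year.
#'
#' @param evals named list of `cv_evaluation` objects, one per year.
#' @return feature x year matrix.
#' @export
importance_table <- function(evals) {
  stopifnot(length(evals) >= 1)
  features <- names(evals[[1]]$importance)
  out <- sapply(evals, function(ev) {
    imp <- ev$importance[features]
    if (!is.null(ev$selection_freq))
      imp[ev$selection_freq[features] <= 0.5] <- NA_real_
    imp
  })
  rownames(out) <- features
  out
}

#' Run the full synthetic per-year analysis
#'
#' Generates the synthetic inputs, computes SMR by indirect
#' standardization, imputes missing indicator values, and for each year
#' fits the linear model, the random forest and the Boruta-fed random
#' forest under repeated k-fold CV, builds the entropy-thresholded
#' province network and refits with the 4 centrality features appended,
#' and computes the CV-averaged Shapley report. Writes all artifacts and
#' a manifest into `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if absent).
#' @return invisibly, a list with the in-memory results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(...) file.path(out_dir, paste0(...))

  panel_full <- .stage("synth", generate_panel(config$synth))
  mort <- .stage("synth", generate_mortality(config$synth, panel_full))
  panel <- .stage("synth", inject_missing(panel_full, config$synth$missing_rate,
                                          seed = .subseed(config$seed, "mask")))
  .stage("synth", {
    write_panel_csv(panel, path("panel.csv"))
    write_mortality_csv(mort, path("mortality.csv"), path("reference.csv"))
  })
  st <- .stage("smr", smr_table(mort))
  write_smr_csv(st, path("smr.csv"))
  imputed <- .stage("preprocess", impute_mean(panel))

  years <- config$synth$years
  metrics <- list()
  evals <- list()
  shap_values <- list()
  for (yr in years) {
    ylab <- as.character(yr)
    a <- .stage("preprocess", assemble(imputed, st, yr))
    lm_ev <- .stage("models", repeated_cv(a$X, a$y, "lm", k = config$k,
                                          repeats = config$repeats,
                                          seed = .subseed(config$seed, paste0("lm", yr))))
    rf_ev <- .stage("models", repeated_cv(a$X, a$y, "rf", k = config$k,
                                          repeats = config$repeats, config = config$rf,
                                          seed = .subseed(config$seed, paste0("rf", yr))))
    rb_ev <- .stage("models", repeated_cv(a$X, a$y, "rf", k = config$k,
                                          repeats = config$repeats, config = config$rf,
                                          use_boruta = TRUE,
                                          boruta_args = config$boruta_args,
                                          seed = .subseed(config$seed, paste0("rb", yr))))
    evals[[ylab]] <- rb_ev
    m <- list(
      linear_model = list(mae_mean = lm_ev$mae_mean, mae_sd = lm_ev$mae_sd,
                          pearson_r = lm_ev$pearson_r, p_value = lm_ev$p_value),
      random_forest = list(mae_mean = rf_ev$mae_mean, mae_sd = rf_ev$mae_sd,
                           pearson_r = rf_ev$pearson_r, p_value = rf_ev$p_value),
      random_forest_boruta = list(mae_mean = rb_ev$mae_mean, mae_sd = rb_ev$mae_sd,
                                  pearson_r = rb_ev$pearson_r, p_value = rb_ev$p_value))
    if (config$network) {
      net <- .stage("network", threshold_scan(spearman_abs_matrix(a$X)))
      feats <- .stage("network", centrality_features(net))
      Xa <- .stage("network", augment_panel(a$X, feats))
      net_ev <- .stage("network", repeated_cv(Xa, a$y, "rf", k = config$k,
                                              repeats = config$repeats,
                                              config = config$rf,
                                              seed = .subseed(config$seed, paste0("net", yr))))
      write_network(net, path("network_", yr, "_edges.tsv"),
                    path("network_", yr, "_entropy.csv"))
      write.csv(feats, path("network_", yr, "_centrality.csv"), row.names = FALSE)
      m$random_forest_network <- list(mae_mean = net_ev$mae_mean,
                                      mae_sd = net_ev$mae_sd,
                                      threshold = net$threshold,
                                      mae_shift = net_ev$mae_mean - rf_ev$mae_mean)
    }
    if (config$shap_repeats > 0) {
      sr <- .stage("explain", shap_cv(a$X, a$y, config = config$rf, k = config$k,
                                      repeats = config$shap_repeats,
                                      seed = .subseed(config$seed, paste0("shap", yr))))
      shap_values[[ylab]] <- sr
      write.csv(data.frame(province_id = rownames(sr$values), sr$values,
                           check.names = FALSE),
                path("shap_", yr, ".csv"), row.names = FALSE)
      m$shap_top_features <- utils::head(sr$ranking$feature, 5)
    }
    metrics[[ylab]] <- m
  }

  imp_tab <- .stage("report", importance_table(evals))
  write.csv(data.frame(feature = rownames(imp_tab), imp_tab, check.names = FALSE),
            path("importance.csv"), row.names = FALSE)

  map_vals <- .stage("report", {
    prov <- sort(panel$provinces)
    smr_avg <- tapply(st$smr, st$province_id, mean)[prov]
    layers <- cbind(smr = smr_avg)
    for (ind in intersect(config$map_indicators, imputed$indicators)) {
      j <- match(ind, imputed$indicators)
      layers <- cbind(layers,
                      rowMeans(imputed$values[match(prov, imputed$provinces), j, ,
                                              drop = FALSE], dims = 1))
      colnames(layers)[ncol(layers)] <- ind
    }
    normalized_average_map(layers)
  })
  write.csv(data.frame(province_id = names(map_vals), combined = unname(map_vals)),
            path("map_values.csv"), row.names = FALSE)

  jsonlite::write_json(metrics, path("metrics.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(package_version = as.character(utils::packageVersion("smrnet")),
                   seed = config$seed, years = years,
                   n_provinces = config$synth$n_provinces,
                   repeats = config$repeats, k = config$k,
                   timestamp = format(Sys.time(), tz = "UTC"),
                   files = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$files) <- files
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE)
  invisible(list(metrics = metrics, importance = imp_tab, smr = st,
                 shap = shap_values, map = map_vals))
}
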