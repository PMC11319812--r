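# smrnet

Spatial analysis of cause-specific provincial mortality: how much excess
mortality does each province carry, which environmental and
socio-economic indicators predict it, and how robust and explainable is
that prediction?

The package is aimed at epidemiologists and biostatisticians working
with aggregate registry data (mortality counts by province and age
class) and indicator panels (pollution, urban environment,
socio-economic context, comorbidity mortality). It implements, as
tested, reproducible building blocks:

* **SMR by indirect standardization** — for province $m$,
  $\mathrm{SMR}_m = O_m/E_m$ with $E_m = \sum_i R_i n_{mi}$ and
  $R_i = M_i/N_i$ the reference age-specific rates; SMR > 1 means
  mortality above the reference level.
* **All-relevant feature selection** — a from-scratch Boruta: shadow
  (permuted) copies of every feature, per-tree out-of-bag permutation
  importance Z-scores, hits against the maximum shadow Z-score, and a
  two-sided Binomial(runs, ½) decision at Bonferroni-corrected α.
* **Prediction** — ordinary least squares and a random forest (600
  trees, ⌈S/3⌉ candidate features per split) under 5-fold
  cross-validation repeated 100 times, scored by mean absolute error and
  the pooled out-of-fold Pearson correlation.
* **Robustness via a province similarity network** — absolute Spearman
  similarity between province indicator profiles, hard-thresholded at
  the threshold maximizing the Shannon entropy of the betweenness
  distribution; degree, betweenness, closeness and eigenvector
  centrality are appended as extra features to verify the model does not
  move.
* **Explanation** — interventional Shapley values for the forest
  (exact subset enumeration for ≤15 features, a polynomial-time tree
  traversal otherwise), averaged over the repeated CV, plus global
  mean-decrease-impurity importance.
* **Synthetic data** — a generator producing indicator panels
  (107 provinces × 31 indicators × 5 years, five thematic categories,
  latent-factor correlation, MCAR missingness) and age-stratified
  mortality with planted effects, so the full pipeline runs and is
  testable without access to registry downloads.

## Worked example

```r
library(smrnet)

cfg    <- synthetic_config(seed = 42)        # 107 provinces, 31 indicators, 2015-2019
panel  <- generate_panel(cfg)
deaths <- generate_mortality(cfg, panel)
smr    <- smr_table(deaths)
head(smr, 3)
#>   province_id year o_m      e_m       smr
#> 1        P001 2015 149 156.3430 0.9530329
#> 2        P002 2015  62 102.1175 0.6071440
#> 3        P003 2015 319 241.8081 1.3192279
```

P003 has an SMR of 1.32: 319 deaths observed against 242 expected from
the reference age-specific rates, a 32% excess. The default generator
plants a threshold effect on `air_o3`, a linear effect on `air_no2` and
a negative effect on `patho_circulatory`; selection and modelling
recover exactly that:

```r
xy  <- assemble(impute_mean(inject_missing(panel, cfg$missing_rate, seed = 42)), smr, 2015)
sel <- boruta_run(xy$X, xy$y, max_runs = 30, seed = 42,
                  rf_params = rf_config(n_trees = 300, min_node_size = 5))
confirmed_features(sel)
#> [1] "air_o3"            "air_no2"           "patho_circulatory"

ev <- repeated_cv(xy$X, xy$y, "rf", repeats = 5, use_boruta = TRUE,
                  config = rf_config(n_trees = 300, min_node_size = 5),
                  boruta_args = list(max_runs = 20,
                                     rf_params = rf_config(n_trees = 150, min_node_size = 5)),
                  seed = 42)
ev
#> cv_evaluation: RF + Boruta, 5-fold CV x 5 repeats
#>   MAE 0.2850 +/- 0.0158;  pooled Pearson r = 0.842 (p = 4.9e-145)
```

The Boruta-fed forest predicts held-out provinces with a mean absolute
SMR error of 0.29 and a strongly significant pooled correlation. The
similarity network and the Shapley report close the loop:

```r
net <- threshold_scan(spearman_abs_matrix(xy$X))
net
#> province_network: 107 nodes, 5644 edges at threshold 0.0016 (entropy 6.741 bits)

sr <- shap_cv(xy$X, xy$y, config = rf_config(n_trees = 200, min_node_size = 5),
              repeats = 1, seed = 42)
sr
#> shap_report: 107 provinces x 31 features over 1 repeats
#>   top features by mean |SHAP|:
#>     air_no2                      0.20511
#>     air_o3                       0.18286
#>     patho_circulatory            0.07800
#>     air_pm10                     0.02996
#>     soil_nitrates                0.01268
```

The two planted pollutant drivers top the attribution ranking and the
comorbidity indicator follows with the opposite sign (high circulatory
mortality, low SMR). `run_pipeline(pipeline_config(...), "out/")`
executes the whole per-year workflow — models, network variant, SHAP,
importance tables, combined min-max map — and writes CSV/JSON artifacts
plus a manifest; `inst/scripts/run_pipeline.R` wraps it for the shell.
See the methods vignette (`vignettes/smrnet-methods.Rmd`) for the models,
conventions and numerical choices.

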