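---
title: "Methods: provincial SMR modelling with forests, Boruta and similarity networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: provincial SMR modelling with forests, Boruta and similarity networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

smrnet implements a spatial-epidemiology workflow for cause-specific
provincial mortality: quantify each province's excess mortality as a
standardized mortality ratio (SMR), regress it on an environmental and
socio-economic indicator panel, select the all-relevant predictors, check
the robustness of the fit against derived network features, and attribute
individual predictions to indicators with Shapley values. This vignette
documents the models, the conventions and the numerical choices; the
README shows a worked example.

## Standardized mortality ratio

For province $m$, $\mathrm{SMR}_m = O_m / E_m$, where $O_m$ is the
observed death count and
$E_m = \sum_i R_i\, n_{mi}$ is the count expected if the reference
population's age-specific rates $R_i = M_i / N_i$ applied to the
province's age structure $n_{mi}$ (indirect standardization). SMR $> 1$
means mortality above the reference level. Conventions:

* The reference is the pooled population over all provinces (a "national"
  reference), supplied explicitly as an age-class table so the operation
  stays pure.
* Age resolution is 18 five-year classes by default; a convention, since
  registry SMRs are rarely published with the class resolution attached.
* $E_m = 0$ is a hard error, not an infinite SMR: it can only arise from
  an empty province.
* SMR is computed per year; there is no temporal smoothing. The analysis
  is deliberately spatial — year-to-year variation in the indicators is
  treated as noise around a stationary spatial pattern.
* No confidence intervals (Byar or exact Poisson) are attached; the
  downstream models consume the point ratio.

## Synthetic data generator

Real provincial panels of this kind are assembled from registry and
monitoring-agency downloads; the generator replaces them with data whose
statistical structure matches what the analysis assumes, so that every
stage is testable offline.

* **Panel.** 107 provinces x 31 indicators x 5 years (2015–2019) by
  default. Indicators belong to five categories (air pollution, soil
  pollution, urban environment, socio-economic, other pathologies). Each
  category has one latent province factor; indicator $j$ of category $c$
  is $\sqrt{\rho}\,Z_{pc} + \sqrt{1-\rho}\,\varepsilon_{pj}$, so `indicator_correlation`
  ($\rho$, default 0.3) is exactly the within-category correlation and a
  single knob. Values are stationary across years up to jitter
  (`panel_jitter_sd`, default 0.05).
* **Mortality.** Province populations are log-normal around 420,000 with
  a pyramid that tapers over the last five age classes. Reference rates
  are log-linear in age class, scaled to a national crude rate of
  4.4/10,000 — the order of magnitude of dementia mortality, yielding
  roughly 100–300 expected deaths per province so that Poisson noise on
  the log-SMR scale is realistically small (~0.07–0.1).
* **Planted effects.** Observed deaths are
  $O_m \sim \mathrm{Poisson}(E_m e^{\eta_m})$ with
  $\eta_m = \sum_k \beta_k\, g_k(z_{mk}) + \mathcal N(0, \texttt{noise\_sd})$,
  $z$ the per-year standardized indicator and $g$ linear, threshold
  ($z > 0.5$) or quadratic, each centered. The true log-SMR therefore
  equals the planted predictor in expectation. Default conditions plant a
  threshold "O3-like" effect (0.5), a linear "NO2-like" effect (0.4) and a
  negative linear comorbidity effect (0.3) emulating the inverse
  SMR–circulatory-mortality association seen in mortality (not incidence)
  data.
* **Missingness** is MCAR (`missing_rate`, default 5%); real missingness
  mechanisms in agency data are undocumented, so nothing fancier is
  defensible.

What the generator does **not** emulate: spatial autocorrelation on a map,
real Italian geography or coding, true pollutant distributions, and
reporting artifacts. Passing tests therefore demonstrate the correctness
and statistical behaviour of the pipeline under its own assumptions, not
epidemiological validity on real data.

## Imputation and assembly

Missing cells are filled with the mean of the observed values of the same
indicator in the same year. This happens globally, before
cross-validation, reproducing the original workflow; it leaks a small
amount of fold information, so `repeated_cv(impute_within_folds = TRUE)`
offers the leak-free variant (training-fold means only). Features are not
scaled: forests are scale-invariant and the linear model is used as an
unregularized baseline.

## Boruta all-relevant selection

Implemented from scratch around per-tree permutation importance:

1. Every feature gets a shadow copy (an independent row permutation).
2. A forest is fitted on originals + shadows.
3. Per tree, the out-of-bag squared error is recomputed with one feature
   permuted at a time; the Z-score is mean/sd of the per-tree loss
   (sd = 0 gives Z = 0 by convention; a forest needs at least 2 trees).
4. A feature scores a *hit* when its Z exceeds the maximum shadow Z
   (MZSA) of that run.
5. Accumulated hits over runs follow Binomial(runs, 0.5) under the null;
   a two-sided test at Bonferroni-corrected $\alpha$ (default 0.05 over
   the initial feature count) confirms features above the 0.5 expectation
   and rejects those below. Rejected features leave the forest, which
   speeds convergence; features undecided after `max_runs` (default 100)
   stay tentative and are **not** selected.

The significance level, run count and tentative policy are conventions
of the classical algorithm, exposed as arguments. Note the symbol clash
in common descriptions of this workflow: the forest size (600 trees) and
the Boruta run count are different quantities; here they are `n_trees`
and `max_runs`.

## Learning framework

Two regressions of SMR on the (selected) indicators: ordinary least
squares, and a random forest with 600 trees and $F = \lceil S/3 \rceil$
candidate features per split (integer rounding is our choice; trees are
fully grown, bootstrap resampling). Evaluation is 5-fold cross-validation
repeated 100 times with fresh random partitions; every province is
predicted exactly once per repeat. Reported metrics: mean absolute error
$\frac1n \sum |A_i - P_i|$ per repeat (mean ± sd over repeats — the ±
choice is ours, the convention is not fixed), and the Pearson correlation
between pooled out-of-fold predictions and actuals with its two-sided
p-value. When Boruta runs inside the CV it sees only the training fold;
if it confirms nothing, the fold falls back to all features. Global
importance is mean decrease impurity, normalized to sum to 1 per fit,
averaged over fits with unselected features scoring 0; a feature counts
as "selected for a year" when confirmed in more than half of the fits.

## Province similarity network

A robustness device: derive purely relational features and check they do
not move the model.

* Similarity $d_{ij}$ = absolute Spearman correlation between the
  31-indicator vectors of provinces $i$ and $j$ (average ranks on ties).
  The absolute value makes strongly anti-correlated provinces maximally
  similar — a semantics inherited from co-expression network practice.
  Because within-province ranks mix the indicators' native units, an
  optional per-indicator z-scoring flag exists (`zscore = TRUE`).
* Hard thresholding: $C_{ij} = 1$ iff $d_{ij} \ge th$, $i \ne j$. The
  threshold is chosen to maximize the Shannon entropy of the betweenness
  distribution. The betweenness values are normalized to a probability
  distribution before the entropy is taken — with raw values the
  objective is not scale-free; this is a deliberate interpretation.
  Candidates are all distinct off-diagonal similarities (every attainable
  adjacency matrix); ties break toward the smallest threshold, i.e. the
  densest network. Networks are built per year from the imputed matrix,
  matching the per-year modelling design.
* Features: degree, Freeman betweenness, closeness
  $(N-1)/\sum_j s_{ij}$ — computed within a node's component and scaled
  by $(n_c-1)/(N-1)$ on disconnected graphs (Wasserman–Faust), isolated
  nodes get 0 — and eigenvector centrality as the principal eigenvector,
  nonnegative with unit Euclidean norm. Power iteration runs on $C + I$:
  the unit shift leaves eigenvectors unchanged but prevents the
  oscillation that plain adjacency iteration exhibits on bipartite graphs
  (a star never converges otherwise); tolerance 1e-10, uniform start. On
  disconnected graphs this selects the component with the largest
  spectral radius.

The four features are appended as a "Network" category and the CV is
repeated; the expected outcome (reproduced in the acceptance suite) is a
MAE shift smaller than the across-repeat MAE standard deviation.

## Shapley attribution

`shap_exact()` enumerates all feature subsets with factorial weights
$|F|!(|S|-|F|-1)!/|S|!$; the value function is the interventional
expectation — mean prediction over a background sample with the coalition
features fixed to the explained row (the conditional-expectation
convention is not fixed by the defining formula; interventional is the
standard for tree models). Enumeration is capped at 15 features.

`shap_fast()` computes the same quantity for a forest in polynomial time:
for each (explained row, background row, tree) triple, one traversal
assigns each leaf's value to the features whose coalition membership
decides whether the hybrid sample reaches that leaf, with closed-form
weights $(a-1)!\,b!/(a+b)!$. It matches the enumeration oracle to
machine precision and satisfies efficiency (values + base = prediction)
exactly; symmetry and dummy follow from the game.

Under cross-validation (`shap_cv()`), values are computed only
out-of-fold with the training fold as background (subsampled to
`background_cap = 100` rows), then averaged per province over repeats;
features are ranked by mean |SHAP| across provinces, the usual
summary-plot ordering. The per-fold aggregation scheme (out-of-fold only,
training-fold background) is our choice; published workflows rarely pin
it down.

## Reporting

`run_pipeline()` executes generation → SMR → imputation → per-year
{LM, RF, RF+Boruta, network variant, SHAP} → tables, writing CSV/JSON
artifacts and a manifest with seeds and file hashes; a rerun with the
same master seed produces byte-identical metrics. The combined map layer
min-max-normalizes the SMR surface and chosen pollutant indicators to
[0, 1] and averages them; constant layers are mapped to zero with a
warning.

## Determinism and problem sizes

All randomness flows from one master seed through deterministic per-stage
sub-seeds (including the C++ permutation RNG), so every operation is
independently reproducible. The test and acceptance suites run the same
code at desk scale: 10 CV repeats instead of 100, importance forests of
150–300 trees where many thousands of fits are needed, Boruta at 20–50
runs, and SHAP over 1–2 repeats. These sizes are the package's test
design; the defaults users get (`repeats = 100`, 600 trees,
`max_runs = 100`) are the reference configuration. One caveat observed
during development: Boruta Z-scores from very small forests (~100 trees)
are noisy enough to leave genuinely informative features tentative;
selection studies should keep importance forests at 300+ trees.

## Known limitations

* Mean imputation before CV leaks fold information (kept as the reference
  behaviour; flag available).
* The similarity network treats anti-correlated provinces as similar, by
  construction.
* MDI importance is biased toward high-cardinality features; all
  synthetic indicators are continuous, so the comparison is fair here,
  but mixed-type real panels would need care.
* No spatial cross-validation: provinces are exchangeable for the CV,
  which understates generalization error in the presence of spatial
  autocorrelation.
* The SMR carries no sampling uncertainty into the regression; provinces
  with small expected counts are as influential as large ones.
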