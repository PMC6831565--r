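# frailmet

Frailty is a state of depleted physiological reserve in older adults, commonly
quantified by a deficit-accumulation **frailty index (FI)**: the fraction of
assessed health deficits an individual exhibits. `frailmet` is an R package
for asking what the blood metabolome looks like across that index — which
metabolites shift between non-frail and frail people, which pathways those
metabolites implicate, how well a small metabolite panel predicts frail
status, and whether a candidate metabolite (e.g. circulating carnitine) is
*causally* linked to frailty.

The package implements the full analysis chain as composable,
tibble-in/tibble-out functions:

1. **Frailty scoring** — `compute_fi()` (FI = deficits present / items
   answered, with a minimum-response rule), `stratify_fi()` into the standard
   classes `[0, 0.1)`, `[0.1, 0.2)`, `[0.2, 0.3)`, `[0.3, 1]`, and
   `fit_fi_regression()`, a Huber M-estimation fit of FI ~ age reporting
   slope, intercept, SSE and unweighted R².
2. **LC-MS preprocessing** — `qc_spline_correct()` (per-feature cubic
   smoothing spline through pooled-QC intensities vs injection order;
   samples divided by the spline and rescaled to the QC median),
   `rsd_filter()` (drop features with QC RSD > 20 %), `log2_transform()`,
   `zscore()`, and seeded chained-equations imputation with predictive mean
   matching (`impute_missing()`).
3. **Chemometrics** — `pc_dfa()` (PCA followed by Fisher canonical
   discriminant analysis on the scores), `bootstrap_pc_dfa()`,
   `rusboost_train()` / `rusboost_2cv()` (AdaBoost.M2 boosting with random
   undersampling of majority classes, CART weak learners, nested
   cross-validation), and `permutation_null()` for the label-permutation
   null of the classification rate.
4. **Univariate panels** — `mann_whitney_panel()` (frail vs non-frail at
   FI 0.2), `kruskal_panel()` (four FI classes), `bh_fdr()`
   (Benjamini–Hochberg), `correlation_heatmap()`.
5. **Pathway enrichment** — `annotate_mz()` matches feature m/z to
   \[M+H\]+ values of reference metabolites within a ppm tolerance;
   `score_pathways()` scores pathway overlap against a resampled-feature
   null; `build_activity_network()` extracts activity-network modules at an
   evidence cutoff of 3 supporting significant features.
6. **Multivariate ROC** — `mccv_roc()`: Monte-Carlo cross-validation
   (balanced subsample, 2/3–1/3 split, 500 repetitions) with PLS-DA VIP
   feature ranking (7 latent variables, top-12 panel) and percentile AUC
   confidence intervals.
7. **Mendelian randomization** — `filter_instruments()` (LD r² > 0.8
   exclusion), `wald_ratio()`, `ivw()` (fixed-effect inverse-variance
   weighting), and `scale_to_or()` to express the effect as an odds ratio
   per 10 % exposure decrease.

A first-class synthetic-data module (`generate_cohort()`,
`generate_feature_table()`, `generate_mr_summary()`) emulates the
statistical structure this analysis assumes — right-skewed unimodal FI,
age-dependent deficit prevalence, injection-order drift visible in
interleaved QCs, and planted metabolite effects (carnitine/vitamin-E-like
decreases, kynurenine-like increases with frailty) — so the whole pipeline
is testable without any external data. A small synthetic pathway reference
(carnitine shuttle, vitamin E, kynurenine, monosaccharide metabolism; masses
derived from elemental composition) ships in `inst/extdata/toy_reference/`.

## Worked example

```r
library(frailmet)

cohort  <- generate_cohort(cohort_config(n_subjects = 2000, seed = 3))
frailty <- compute_fi(cohort$deficits, min_items = 30)
fi_distribution_summary(frailty$fi)
#> # A tibble: 1 × 9
#>       n   min   max  mean skewness prop_class1 prop_class2 prop_class3 prop_class4
#>   <int> <dbl> <dbl> <dbl>    <dbl>       <dbl>       <dbl>       <dbl>       <dbl>
#> 1  1977     0 0.567 0.166    0.752       0.218       0.448       0.246      0.0880
```

The FI is right-skewed (skewness 0.75) with all four frailty classes
populated, and 23 of 2000 subjects were excluded for answering fewer than 30
items. The age trend is fitted robustly:

```r
d <- dplyr::inner_join(frailty, cohort$subjects, by = "subject_id")
fit_fi_regression(d)
#> Robust FI ~ age regression (Huber M-estimation)
#>   slope      0.004049 FI/year
#>   intercept  -0.122462
#>   SSE        10.8645
#>   R-squared  0.2956  (n = 1977)
```

(The FI rises about 0.004 per year of age; most FI variance is *not*
explained by age, which is exactly why frailty is treated as its own
phenotype.) The one-command demonstration runs every stage — scoring,
drift correction, RSD filtering, univariate panels, enrichment, PC-DFA,
double-CV RUSBoost with a permutation null, multivariate ROC and MR — and
writes each artifact plus an MD5 manifest:

```r
res <- demo_pipeline(dir = "demo_run", seed = 1)
res$classification$correct_rate   # ~0.6-0.7 vs 0.25 four-class chance
res$permutation$p_value           # 0.01 with 99 permutations
glance(res$mr)                    # IVW beta, SE, OR per 10% decrease
```

Rerunning with the same seed reproduces the manifest checksums bit for bit.

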