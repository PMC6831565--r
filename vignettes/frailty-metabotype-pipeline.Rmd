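---
title: "Methods: frailty-index metabotyping with frailmet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frailty-index metabotyping with frailmet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`frailmet` links deficit-accumulation frailty scoring to untargeted
LC-MS metabolomics. This vignette is the package's account of the models it
implements, the defaults it ships, and the choices made where the design was
genuinely open. Every empirical statement here is one the test suite or
`scripts/acceptance.R` computes.

## The frailty index and its stratification

For subject $j$ with answered item set $A_j$ and per-item deficit values
$x_{ij} \in [0,1]$, the frailty index is

$$\mathrm{FI}_j = \frac{\sum_{i \in A_j} x_{ij}}{|A_j|},$$

with subjects excluded when $|A_j|$ falls below `min_items` (default 30 of a
60-item panel, the standard inclusion rule). Item coding — which answers map
to which fractional values — is data-driven: `compute_fi()` accepts any
values in $[0,1]$, so a coding table can be applied upstream.

Stratification uses the conventional four categories with edges
$(0.1, 0.2, 0.3)$. The published category labels ("<0.1", ">0.3") do not
resolve what happens *on* an edge; `frailmet` fixes bins as left-closed,
right-open except the last — $[0,0.1)$, $[0.1,0.2)$, $[0.2,0.3)$,
$[0.3,1]$ — so FI = 0.1 falls in class 2. The edges are an argument
everywhere they matter.

The FI ~ age trend is fitted by Huber M-estimation (`MASS::rlm`, tuning
constant $k = 1.345$ on the MAD residual scale), which coincides with
ordinary least squares exactly when no residual crosses the Huber threshold
(a property the tests verify on constructed data). SSE and $R^2 = 1 -
\mathrm{SSE}/\mathrm{SST}$ are reported **unweighted** over all
observations so the pair is well-defined regardless of the robustness
weights.

## What the synthetic cohort emulates

`generate_cohort()` draws ages uniformly on 50–90 years and item responses
from a per-item Bernoulli with logistic dependence on age,

$$p_{ij} = \mathrm{logit}^{-1}\!\big(\alpha_i + b_j + \beta_{\mathrm{age}}(\mathrm{age}_j - 70)\big),$$

with item intercepts $\alpha_i \sim N(-1.8, 0.7^2)$, subject liability
$b_j \sim N(0, 0.45^2)$ and $\beta_{\mathrm{age}} = 0.035$ per year. This is
the simplest mechanism producing the three features population frailty
surveys report: a right-skewed unimodal FI, a positive FI–age correlation,
and occupancy of all four classes in roughly the proportions
26/48/18/8 % reported for community cohorts — the defaults were calibrated
once against those proportions and then frozen. Item non-response is MCAR
at 2 %, plus 1 % of subjects answering under half the panel so that the
minimum-response exclusion path is exercised.

What the generator does **not** emulate: item redundancy structure
(real deficits correlate beyond a single liability), informative
missingness, survey weighting, and longitudinal attrition. Passing tests
therefore demonstrate correctness of the *machinery* on data with the
assumed statistical shape, not robustness to those real-data violations.

`generate_feature_table()` builds an injection sequence in which a pooled QC
leads, trails, and punctuates each batch every `qc_interval` study samples.
The published protocols rarely state QC frequency; the default is 10, a
common bracketing density, and configurable. Each feature has a latent base
intensity (log2 uniform 14–22); QCs share it exactly plus technical noise
(log2 SD 0.1), samples add biological noise (log2 SD 0.8) and any planted
class effect; drift multiplies the whole run by a smooth shared curve
(linear or single-period sinusoid) with per-feature amplitude jitter
(×U(0.5, 1.5)). Planted features take reference \[M+H\]+ masses
(neutral monoisotopic mass + 1.007276 Da) so annotation can rediscover
them; the default plant is five decreasing carnitine/vitamin-E species and
two increasing kynurenine-pathway species at 0.8 log2 units per class step.
Non-planted m/z are uniform on the 100–1000 acquisition range.

## Drift correction, filtering, transformation, imputation

`qc_spline_correct()` fits, per feature and batch, a cubic smoothing spline
to QC intensity vs injection order with leave-one-out cross-validated
smoothing, bounded (`spar` in \[0.2, 1.5\]) so the fit cannot collapse to
interpolation. Correction is **multiplicative** — each intensity is divided
by the spline value at its injection order — because MS signal drift is
predominantly gain-like; whether the original correction was multiplicative
or subtractive is not stated in published protocols, so the choice is
documented here and kept fixed. Rescaling restores the batch QC median
exactly (an invariant the tests assert). Beyond the first/last QC the
spline is clamped to its boundary values to avoid wild extrapolation, and
predictions are floored at 5 % of the QC median so a pathological fit can
never flip signs. Features with fewer than 4 non-missing QC points in a
batch are left uncorrected and flagged.

`rsd_filter()` removes features whose QC relative standard deviation
exceeds 20 % (the conventional untargeted-metabolomics threshold; features
*at* the threshold are retained), and `log2_transform()` guards against
double application via a table attribute. Zeros are replaced by half the
feature's minimum positive value — a common metabolomics convention chosen
here because the source protocols are silent on zeros.

`impute_missing()` implements chained equations with predictive mean
matching by hand (no imputation package is a dependency): each variable is
regressed on all others, each missing cell receives the observed value of
one of 5 nearest-prediction donors, 10 sweeps per imputation, 5 imputations
pooled by per-cell means, all under sub-seeds derived from one seed so
reruns are identical. The simulation tests show pooled PMM beats
column-mean imputation in RMSE on correlated biomarkers with 10 % MCAR
missingness.

## Supervised ordination and classification

`pc_dfa()` performs PCA by SVD, retaining the smallest component count
explaining ≥ 95 % variance (capped at 50) when `pc_count` is not given —
the source literature never states retained components — then Fisher
canonical discriminant analysis on the scores: eigenvectors of $W^{-1}B$
ordered by decreasing between/within variance ratio, at most
(classes − 1) functions. A singular $W$ receives a ridge of
$10^{-8}\,\mathrm{tr}(W)/d$ (floored at $10^{-10}$ for the fully degenerate
case) and the event is reported. At full PC rank the scores equal the
direct Fisher LDA solution up to sign and scale, which the tests check
against an independently coded eigen-solution at tolerance $10^{-8}$.

`bootstrap_pc_dfa()` uses a **stratified** bootstrap (resampling with
replacement within each class): it preserves the supervisory design, makes
degenerate resamples rare, and gives the clean property that duplicated
identical data yield zero centroid dispersion. Out-of-bag samples are
projected through each refit and axes are sign-aligned to the full-data
model. The default is 1,000 resamples for desk-scale runs; the population
convention of 10,000 is available through the argument.

`rusboost_train()` implements AdaBoost.M2 with random undersampling: each
round samples majority classes down to the minority count with probability
proportional to current example weight, fits a depth-limited CART
(`rpart`, `cp = 0`), computes the M2 pseudo-loss over the full training
set, and updates the mislabel distribution. Defaults — 50 learners, depth
3, learning rate 0.1 — are ordinary boosting practice; none are stated in
the source literature. A round with pseudo-loss ≥ 0.5 is redrawn (5
retries) and training stops early if retries are exhausted. With one round
on balanced data the ensemble reduces exactly to a single CART (a
regression test), and with undersampling disabled it is plain multiclass
boosting.

`rusboost_2cv()` nests stratified folds: inner folds (default 2) select
ensemble size and depth from a small grid, outer folds (default 3) supply
the unbiased predictions from which the confusion matrix is assembled;
optional bootstrap refits of the outer-training folds estimate rate
stability. Fold counts and grids are documented defaults, not inferences
about the original analysis. `permutation_null()` permutes labels and
recomputes the same cross-validated rate, reporting
$p = (1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(n_{\mathrm{perm}} + 1)$;
the statistic function is pluggable so calibration studies can use a cheap
classifier.

## Univariate panels and enrichment

The frail/non-frail contrast is Mann–Whitney at the FI 0.2 split (exact
enumeration when both groups ≤ 8 and untied, otherwise the tie-corrected
normal approximation without continuity correction); the four-class
analysis is Kruskal–Wallis; both feed Benjamini–Hochberg q-values
(`stats::p.adjust`). For two classes the Kruskal–Wallis p agrees with the
Mann–Whitney normal-approximation p to $10^{-6}$, which is why the
continuity correction is off. Both p and q are reported because published
significance callouts mix the two conventions.

`annotate_mz()` considers only the \[M+H\]+ adduct at 10 ppm — a deliberate
simplification of full pathway-activity prediction tools (no adduct
combinatorics, no mass clustering), appropriate because the primary ion is
forced and the bundled reference is toy-scale. The significant-feature set
defaults to p < 1e-4. `score_pathways()` draws same-size random feature
sets for its null; `build_activity_network()` keeps annotated metabolites
with evidence ≥ 3 (distinct supporting significant features — a documented
stand-in for the original evidence score, which is not restated in the
source) or membership in a pathway below the significance level, and
reports connected components of the induced reference adjacency as
modules. The bundled reference (23 metabolites, 4 pathways, 20 edges) is
synthetic: memberships follow textbook biochemistry, masses are derived
from elemental composition (`formula_mass()`), and the tests re-derive
every bundled mass from its formula.

## Multivariate ROC

`mccv_roc()` repeats (default 500×): balance groups by undersampling the
majority to the minority count (the balancing mechanism is unstated in the
source; undersampling is the simplest that guarantees balance), split
2/3–1/3 stratified, rank features by PLS-DA VIP on the training part
(NIPALS, 7 latent variables, autoscaled), refit on the top-12 features,
score the held-out third. VIP satisfies $\mathrm{mean}(\mathrm{VIP}^2)=1$
exactly; ties rank by feature index. AUC is the normalised Mann–Whitney
statistic (ties half-counted). The mean curve is a vertical average on a
101-point FPR grid. The CI is the 2.5/97.5 percentile of repetition AUCs
by default; because the original interval could equally have come from an
added bootstrap, `ci_method = "bootstrap"` resamples the repetition AUCs
and intervals their means instead. The calibration test plants four
informative features with per-feature shift
$\delta = \sqrt{2}\,\Phi^{-1}(0.75)/2$, giving a closed-form population AUC
of $\Phi(\sqrt{4}\,\delta/\sqrt{2}) = 0.75$ for the optimal combination,
and requires the recovered mean AUC within 0.05.

## Mendelian randomization

Instruments in LD ($r^2$ strictly above 0.8) are pruned by dropping the
member of each pair with the larger exposure SE — the source kept the more
reliably instrumented SNP of its correlated pair, and exposure precision is
the natural generalisation. Per-SNP Wald ratios
$\hat\beta_j = \Gamma_j/\gamma_j$ carry first-order delta-method SEs
(verified against a $10^6$-draw sampling oracle within 2 %), pooled by
fixed-effect IVW. Pleiotropy-robust estimators (Egger, weighted median) are
out of scope, matching the small-instrument setting.

**Exposure-scale convention (important):** `scale_to_or()` assumes the
pooled $\beta$ is expressed per unit of *natural-log* exposure. The odds
ratio for a relative change $c$ (e.g. $-0.10$ for a 10 % decrease) is then
$\exp(\beta \ln(1+c))$, CI endpoints transformed by the same monotone map.
How a per-allele estimate was converted to "per 10 % decrease" is not
derivable from the published numbers alone, so this package states its
convention explicitly and applies it consistently; summary statistics must
be on (or converted to) the log-exposure scale before pooling. Coverage of
the 95 % interval under the generator's model is verified at 300
replicates.

## Problem sizes, determinism, degenerate inputs

The test suite and acceptance script run at sizes chosen for a single CPU:
cohorts of 400 (2,000 for distribution shape), 200-feature tables,
1,000-or-fewer bootstrap resamples, 99–199 permutations, 300 MCCV
repetitions; all conventions scale up through arguments. Every stochastic
function takes a seed and derives independent sub-streams from it, so the
pipeline manifest (MD5 per artifact) reproduces bit-identically under a
fixed seed — `run_pipeline()` enforces this and the tests assert it.

Degenerate inputs are handled explicitly rather than by accident: constant
predictors error in the regression; all-tied data give p = 1 in the rank
tests; constant features are flagged (z-score zeros, correlation 0);
features absent from QCs skip correction with a report; classes losing all
members abort with a message naming the requirement.

## Known limitations

Annotation is mass-match only (no MS/MS identity), positive mode only; the
pathway reference is deliberately tiny; the imputation model is linear;
LD handling is pairwise; and no attempt is made to reproduce
cohort-specific published coefficients, which depend on restricted survey
and serum data. The package's claims are therefore about the correctness
and calibration of the methods, demonstrated on data whose generating
process is known.
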