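---
title: "Conformal uncertainty quantification for expression-based models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformal uncertainty quantification for expression-based models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conformalgx)
```

## The problem

Expression-based classifiers and regressors in genomic medicine — responder
prediction, molecular subtyping, drug-sensitivity estimation — emit point
predictions whose errors can carry clinical cost. Conformal prediction (CP)
wraps any such model in a distribution-free layer that returns *prediction
sets* (classification) or *intervals* (regression) guaranteed to contain the
truth with a user-chosen probability, assuming only that the evaluation
samples are exchangeable with the reference data (Vovk, Gammerman & Shafer,
*Algorithmic Learning in a Random World*, 2005).

The machinery is rank-based. A **non-conformity score** $\alpha(x, y)$ says
how strange the pair $(x, y)$ looks to a fitted model — here $1 - \hat p(y
\mid x)$ for classifiers (the *inverse probability*, identical to the hinge
convention used by standard CP implementations) or $|y - \hat y(x)|$ for
regressors. A candidate's score is ranked against reference scores to give a
**conformal p-value**

$$ p = \frac{\#\{\alpha_i \ge \alpha_{\text{test}}\} + 1}{n + 1}, $$

and the prediction region at confidence $c$ keeps every label with
$p > \varepsilon = 1 - c$. The API always speaks in *confidence*; the
significance level is derived, never passed, which avoids the recurring
percent-vs-level ambiguity in applied write-ups.

Two schemes are implemented:

* **Transductive (TCP)** — `tcp_predict()`. For each test sample and each
  candidate label the model is retrained on the augmented data and all
  $n + 1$ instances are re-scored; the augmented instance's p-value counts
  itself, so $p \ge 1/(n+1)$. $K$ retrainings per test sample, but no data
  is spent on a calibration split — the economical scheme for small cohorts
  (our binary pipeline, 78 samples).
* **Inductive (ICP)** — `icp_fit()` + `icp_classify()` /
  `icp_regress_predict()`. One fit on a proper training set; a disjoint
  calibration set supplies the reference scores. `icp_fit()` refuses
  overlapping sample ids outright (leakage check).

The **Mondrian, label-conditional** variant (`mondrian = TRUE`) ranks each
candidate label only against calibration samples of that same true label,
which restores per-class validity when class prevalence differs between
calibration and deployment. It requires at least one calibration sample per
class and errors otherwise.

For regression, the interval half-width at confidence $c$ is the $k$-th
smallest calibration residual with $k = \lceil (n_{\text{cal}} + 1)\,c
\rceil$; when $k > n_{\text{cal}}$ the interval is reported *unbounded*
($\pm\infty$) rather than clamped — clamping would silently void the
guarantee.

## Evaluation vocabulary

`coverage_report()` bundles: **empirical coverage** (truth inside the
region/interval), its complement the error rate, the **UNC rate**
(non-singleton regions; the *empty* region counts as uncertain — it is the
layer's way of saying no label conforms), **error detection** (among
base-model misclassifications, the flagged fraction; `NA` when the base
model makes no errors, so a perfect model never masquerades as perfect
detection), and **size-stratified coverage** as the adaptivity diagnostic.
`repeated_split_coverage()` re-splits one cohort many times; under
exchangeability the per-repeat coverage of a split conformal predictor
follows $\mathrm{Beta}(n_{\text{cal}} + 1 - \ell,\ \ell)$ with $\ell =
\lfloor \varepsilon (n_{\text{cal}} + 1) \rfloor$, and the diagnostics
driver (`analysis/05_validity_diagnostics.R`) compares the empirical spread
against that law. A practical consequence worth internalising: with
$n_{\text{cal}} = 200$ at 90% confidence the law is
$\mathrm{Beta}(181, 20)$, which places about 8% of repeats below 0.87 —
per-split coverage a few points under nominal is not a bug but the expected
calibration-size fluctuation.

## Distribution shift

`mmd_permutation_test()` compares two cohorts with the squared maximum mean
discrepancy (Gretton et al., JMLR 2012), Gaussian kernel, bandwidth from the
median pairwise distance of the pooled sample. Choices and why:

* **V-statistic** (biased) rather than U-statistic: non-negative by
  construction; under a permutation null the estimator bias is irrelevant to
  the test's exactness.
* **Bandwidth fixed before permuting**: the pooled median is
  permutation-invariant, so holding it fixed keeps the test exact and saves
  recomputation.
* **p-value** uses the +1 correction, so its floor is $1/(B+1)$.

`exchangeability_check()` reuses the same machinery as an i.i.d. diagnostic:
random halves of one cohort should not differ (median permutation p-value
reported); the `split = "sequential"` mode tests first half against second
half in file order, the layout that catches concatenated multi-site files —
random halves would mix the sites away and see nothing.

## Synthetic cohorts: what they emulate and what they do not

`generator_spec()` draws class-conditional Gaussian expression profiles with
equal spherical covariance: only the first `n_informative` features carry
signal (their indices are recorded in metadata so selection recovery is
testable); the rest are standard normal noise. Class means are seeded
Gaussian draws scaled so the expected squared between-class gap per
informative feature is `separation`² (within-class SD units); `overlap_pair`
plants one transcriptionally close pair (gap contracted to 0.3 of the global
scale) next to a separable class — the two-overlapping-plus-one-separable
geometry typical of lymphoma subtype panels. Regression cohorts use a linear
response over the informative features (weights $1/\sqrt{m}$) with optional
log-normal link; `response_scale` sets the dynamic range, and the IC50-like
preset spans roughly five orders of magnitude.

Preset calibration (chosen once, stated here so they are not mistaken for
tuning knobs): the binary preset (78 samples, 30/200 informative, separation
0.5) puts a tuned SVM near 87–90% accuracy; the lymphoma preset (1032
samples, 345/517/170 class mix, separation 2.1, ABC/GCB overlapping) puts a
boosted-tree base model near 16% error; the external lymphoma cohort is a
*sibling half* of one double-size draw — same class means, fresh noise —
given a mild covariate shift (`apply_shift()`: translation 0.15 SD and 8%
variance inflation on 30% of features), producing an MMD that is small in
magnitude yet detectable at $n \approx 1000$, with only a gentle coverage
and uncertainty response. Drawing the "external" cohort from a different
generator seed would change the class means themselves — concept shift, not
covariate shift.

What the generators deliberately do **not** model: probe-level artifacts,
normalisation pipelines, batch structure, gene–gene correlation, or any
covariance anisotropy. Passing tests therefore certify the *conformal
machinery* — validity, adaptivity, shift response — on exchangeable
Gaussian-profile data, not performance claims about any real cohort.

## Pipelines and their design choices

* **Binary transductive** (`run_binary_tcp()`): MRMR → 80/20 split → small
  SVM cost grid by 5-fold CV → TCP per test patient. Feature selection runs
  on the *full cohort before the split*: the transductive guarantee needs
  all $n+1$ points treated symmetrically, and selecting on the training
  portion alone demonstrably breaks it (we observed ~75% coverage at the
  95% level under train-only selection). The inductive pipelines select on
  the training portion only — there the guarantee rests on
  calibration/test exchangeability, which training-derived transformations
  do not disturb. SVM "probabilities" are a logistic link on the decision
  values: rank-equivalent to the margin (which is all a conformal p-value
  consumes) and reproducible across refits, unlike Platt calibration with
  its internal cross-validation randomness.
* **Multiclass inductive** (`run_multiclass_icp()`): MRMR on train →
  64/16/20 split → XGBoost (single-threaded, seeded) → hinge scores →
  regions on the internal test set and, when an external cohort is given,
  on that cohort plus an MMD audit between the two cohorts'
  selected-feature matrices. Samples labelled `UNC` never enter training or
  calibration; they receive regions and a separate composition table.
* **Regression inductive** (`run_regression_icp()`): log-IQR outlier fence
  (quartiles ± 3 IQR on the log response; conservative, suited to
  heavy-tailed positive responses) → MRMR → random forest →
  absolute-residual calibration at each requested confidence.
  `log_response = TRUE` (default) ranks features against and fits the
  forest on the log response, back-transforming predictions: on log-normal
  responses a raw-scale Pearson screen is dominated by the tail (planted
  genes go unrecovered) and a raw-scale forest cannot extrapolate the tail
  (negative R²). The conformal layer still calibrates raw absolute
  residuals, so intervals remain additive around the prediction. MSE/R² are
  reported on the modelling scale.

Every pipeline writes a config echo (JSON), prediction tables (TSV),
coverage reports (JSON) and a seed log; two runs with one config and seed
are byte-identical.

## Numerical and convention choices

* Non-smoothed p-values (ties counted as $\ge$, +1 correction) are the
  default: deterministic, hence testable; smoothed p-values would buy exact
  uniformity at the cost of injected randomness.
* Empty prediction sets are reported as-is and count as both an error and an
  uncertain case — the flag-for-expert semantics; they are not coerced to
  the argmax label.
* Label order is the lexicographic order of category names everywhere.
* MRMR uses the difference criterion (relevance − mean |correlation| with
  the selected set), F-statistic relevance for categorical labels, |Pearson|
  for continuous. Zero-relevance features (constants included) become
  eligible only after every positive-relevance feature, so a constant can
  never precede an informative gene.
* Splits use largest-remainder allocation (exact partition; stratified
  within class to ±1 sample), all seeded; every function that touches the
  RNG takes a seed and restores the caller's RNG state.

## Known limitations

* Probability-based non-conformity scores *saturate* off-distribution:
  under a strong covariate shift a softmax or tree model often grows more
  confident (wrongly), so the UNC rate need not rise and coverage quietly
  decays. A distance-type score (`centroid_distance_measure()`) instead
  maps off-distribution points to empty regions, which is the behaviour to
  reach for when shift-flagging is the goal; the shift-grid diagnostic in
  `analysis/05_validity_diagnostics.R` uses it for exactly that reason.
  Weighted CP under covariate shift is out of scope.
* The absolute-residual regression score is not locally adaptive: one
  half-width serves all test samples, generous in the bulk and tight in the
  tail of a heavy-tailed response. Normalised or Mondrian conformal
  regression would address this and is out of scope.
* Marginal coverage is the guarantee; conditional (per-subgroup) coverage
  is only diagnosed (SSC, Mondrian per-class checks), never certified.
* Problem sizes in tests and diagnostics (e.g. 100 split repeats; cohorts
  of 1–4k samples) were chosen as the smallest at which the distributional
  checks have useful resolution.
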