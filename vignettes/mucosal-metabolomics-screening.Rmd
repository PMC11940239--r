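---
title: "Screening and validating case-control metabolomics signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening and validating case-control metabolomics signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaboscreen)
```

## Scope and model

`metaboscreen` analyzes a samples × metabolites abundance table from an
untargeted LC-MS case-control study. The emulated design is 44 cases
(IBS patients, with IBS-C/IBS-D subtypes) against 69 controls. The package
covers four stages — preprocessing, fold-change/volcano screening, Random
Forest validation with a Y-scrambled null, and cohort characteristics —
plus a synthetic-data generator that makes all of them testable without
patient data. Spectral processing (peak picking, compound identification)
is upstream of the package and out of scope.

## Preprocessing

Three switchable steps, applied in order:

* **Sample normalization** (default: median). Each sample is divided by its
  median positive intensity, then multiplied by the grand median of the
  sample medians so values stay on an intensity-like scale. This removes
  per-sample multiplicative effects; note that the grand-median factor
  itself depends on the sample set, so normalization is invariant to
  per-sample rescaling only up to one global constant (relative abundances,
  fold changes and all downstream statistics are unaffected). Sum
  normalization and "none" are available.
* **Log transform** (default: log10). The pseudo-count defaults to half the
  smallest positive value when the table contains zeros — the standard
  remedy — and to 0 otherwise, keeping the transform exact on strictly
  positive data.
* **Scaling** (default: autoscale, i.e. unit variance). Columns are
  centered and divided by the sample SD (n−1 denominator, the convention of
  the MetaboAnalyst-style ecosystem). Zero-variance columns are centered
  only and flagged. Pareto scaling and centering-only are available.

The named upstream tooling does not pin down which variants were used, so
each step is explicit configuration rather than a buried constant.

## Differential screen

Fold change is the ratio of arithmetic group means computed on
**normalized, pre-log** abundances — the scale on which a mean ratio is
meaningful — while the two-sided **Welch** t-test runs on
**log-transformed** abundances, the variance-stabilized scale. Welch rather
than Student because the groups are unbalanced (44 vs 69) and there is no
variance-homogeneity justification. Both scales are configurable since
neither is externally fixed. BH-FDR is computed over all metabolites of the
contrast with no pre-filtering. The volcano gates are `|log2FC| >= 1`
(exactly FC ≥ 2 or ≤ 0.5) and `p < 0.05` (−log10 = 1.30); a metabolite is
highlighted only when it passes both, which is why a strongly significant
but small-magnitude feature (the glycine-like case) is deliberately not
highlighted. The same machinery serves the subtype contrast, oriented
IBS-D over IBS-C so that elevated-in-IBS-D features get positive log2FC.

Degenerate inputs: a metabolite with zero variance in both groups gets
p = 1 when the means agree (flagged) and p = 0 in the perfect-separation
limit; a zero denominator-group mean yields an undefined-FC flag and the
feature is excluded from volcano annotation with a warning.

## Random Forest validation

Each of `n_iterations` (default 100) repetitions draws a fresh stratified
70/30 split (per class, `round(0.7 × class size)` to training — 31 cases +
48 controls at the study size). Two arms run the identical procedure:

* **Real arm** — 2-fold stratified inner CV selects hyperparameters by mean
  validation AUC from a grid over mtry ∈ {⌈√m⌉, ⌈m/3⌉}, trees ∈ {250, 500},
  depth ∈ {unlimited, 8}, minimum leaf ∈ {1, 5} (16 points; the four
  conventionally tuned forest hyperparameters at desk scale, overridable).
  Ties break toward the simpler model: fewer trees, shallower depth
  (unlimited counts as deepest), larger leaves, smaller mtry, then grid
  order. The forest (the `ranger` implementation) is refit on the full
  training split; the test AUC is the rank-based (Mann–Whitney) AUC of the
  predicted case probabilities, ties counting 1/2.
* **Scrambled arm** — the *training* labels are replaced by a uniform
  permutation of their multiset; the test labels stay real. This is the
  standard Y-scrambling contract: a model trained on label noise must score
  ≈ 0.5 on intact test labels, and the arm re-runs the entire procedure,
  including an independent hyperparameter search.

**Permutation importance**: for each feature, one independent permutation
of its test-data column (all other columns untouched), model re-scored,
1−AUC recorded. One permutation per feature per iteration suffices because
the 100 outer repetitions absorb permutation variance. Per arm, the
per-feature 1−AUC medians and the unpermuted baseline (1 − test AUC) are
summarized with percentile bootstrap 95% CIs of the median (default 1000
resamples); a feature is **significant** when its interval is disjoint from
the same arm's baseline interval, and the ranking orders features by real-arm
median 1−AUC descending.

Randomness is governed by one master seed that spawns per-iteration,
per-arm, per-purpose streams (split, scramble, grid search, fit,
permutation, bootstrap), so identical data + config reproduce the result
exactly while the arms stay independent.

### What the null arm can and cannot certify

The bootstrap CIs are taken over repeated splits of *one* dataset. They
capture split-to-split variance, not dataset-to-dataset variance: on a
finite effect-free dataset, spurious sample-level group differences are
shared by training and test subsets, so the real arm's median AUC — and its
narrow CI — can sit away from 0.5 for that particular dataset even though
it is centered on 0.5 across datasets. The package's tests therefore assert
null calibration *marginally* (the mean of per-dataset median AUCs over
replicate effect-free datasets is ≈ 0.5 for both arms) rather than
demanding that every single-dataset CI covers 0.5. The scrambled arm is far
more stable — scrambling destroys the train-side association each
repetition — and at the full study scale (100 iterations, 300 features) its
median AUC lands around 0.49–0.50 with a CI of roughly ±0.03.

## Synthetic-data generator

The generator is first-class, tested code, not a fixture. Per metabolite, a
natural-log location is drawn once from `baseline_log_mean_range` (default
log(1e4)–log(1e6), typical LC-MS intensity magnitudes); within-group
abundances are log-normal with log-scale SD `sqrt(log(1 + cv^2))`. Effects
are planted multiplicatively — case mean = control mean × 2^log2FC — so the
fold-change definition recovers them exactly in expectation; a planted
log2FC of 0 leaves the groups identically distributed. Features are
independent by default (no correlation model is externally specified); an
equicorrelated-block option and a missing-at-random rate exist but default
off. Covariates (sex, age, body mass, height, BMI, diabetes, hypertension)
are drawn per group from the published cohort marginals; the IBS-C/IBS-D
split among cases is not published and defaults to 50/50. BMI is drawn from
its own marginal rather than derived from mass and height — adequate for
testing the table machinery, not for studying covariate dependence.

The within-group coefficient of variation is a free parameter — the source
study reports no variance estimates — fixed once at **cv = 1.0**, a
realistic value for untargeted LC-MS intensities that makes the planted
log2FC ≈ 1.0–1.6 effects reliably detectable at n = 44/69 (on the log10
scale, a log2FC of 1.63 is ≈ 0.6 SD units there). What passing tests show
is that the *pipeline machinery* recovers effects of the published
magnitude under clean log-normal noise; real biopsy data add correlation
structure, heavy tails, batch effects and missingness the generator
deliberately omits, so test results do not certify performance on real
tissue data.

## Cohort characteristics

Categorical variables: per-group "N (%)" and the two-sided Fisher exact
test under the probability-mass definition (sum of hypergeometric
probabilities ≤ that of the observed table) — the convention that
reproduces the published table's p-values (0.175 for sex, 0.783 for
diabetes, 0.169 for hypertension) from the printed counts alone. Continuous
variables: "Mean (SD)" and the two-sided Wilcoxon rank-sum test (exact for
small tie-free samples, tie- and continuity-corrected normal approximation
otherwise). The published continuous p-values depend on unreleased
per-subject values, so they are reproducible only in distributional shape,
not numerically. Display rounding: percents to 0 d.p., p to 3 d.p. A
single-level variable is reported without a test and flagged.

## Problem sizes used by the tests and acceptance script

The acceptance script and the study-scale test run the full published
procedure: 44/69 samples, 300 metabolites, three planted effects
(log2FC 1.63, 1.08, −1.52), 100 iterations, the 16-point default grid, 1000
bootstrap resamples. Property-style tests run the same code at reduced
sizes chosen for tight feedback loops: recovery checks use 30 metabolites,
15 iterations and a single-point grid; exhaustive oracle comparisons
(Fisher vs hypergeometric enumeration, BH vs step-up definition, rank AUC
vs trapezoidal ROC, Wilcoxon vs rank-assignment enumeration) run on all
small instances where enumeration is exact.

## Known limitations

* No covariate-adjusted differential models (the emulated study fits none
  despite its age imbalance); the cohort table is descriptive only.
* The generator's independence and log-normality assumptions are idealized;
  see above.
* Binary-outcome AUC only; no multiclass support.
* The forest is consumed behind a minimal fit/predict-scores contract
  (`ranger` supplies it); impurity-based or SHAP importances are out of
  scope — importance is permutation 1−AUC by design.
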