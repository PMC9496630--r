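---
title: "Methods: ensemble weighted-voting screening from serum GC-MS metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble weighted-voting screening from serum GC-MS metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emlscreen)
```

This vignette is the package's own account of the model it implements, the
assumptions behind it, the parameters that matter, and the choices made where
the design was genuinely open. It states no empirical result that the test
suite or the analysis scripts do not themselves compute.

## The screening model

A serum sample is represented by a GC-MS peak table row: one peak area per
metabolite signal plus the peak area of a spiked internal standard (IS). The
screening decision for endometrial cancer (EC) versus control (CTRL) is made
by an ensemble of seven classifier families. Each admitted model $m$ casts a
signed, weighted vote on sample $x$:

$$v_m(x) = s_m(x)\, \cdot\, 100 \cdot a_m \cdot c_m(x), \qquad
\mathrm{EML}(x) = \sum_m v_m(x),$$

where $s_m(x) = +1$ if model $m$ predicts EC and $-1$ for CTRL, $a_m$ is the
model's cross-validation accuracy, and $c_m(x) \in [0,1]$ is its confidence —
a distance-from-boundary measure that is 0 exactly on the model's decision
boundary and 1 at certainty. The construction makes the score of a
hypothetical sample with balanced votes (equal number and weight for and
against EC) exactly zero, and bounds a $k$-model ensemble by $\pm 100k$.

Two elements of the voting rule are not fully pinned down by its verbal
description and are fixed here as package design choices:

* **Vote scale 100.** Published score distributions for a seven-model
  ensemble run in the hundreds (class means of tens to hundreds, extremes
  near $\pm 500$, thresholds around 200), consistent with per-model votes of
  at most $\pm 100$; the raw $a_m c_m$ product alone would bound the ensemble
  at $\pm 7$. The scale is exposed as a parameter.
* **Multiplicative weight** $a_m \cdot c_m$. The votes are "weighted using
  both" accuracy and confidence; the product is the minimal combination that
  is zero exactly at the boundary and maximal only when both factors are
  maximal. An additive combination would let a low-confidence vote from an
  accurate model outweigh a certain one.

The decision threshold generalizes the defining sign convention
(score $> 0$ ⇒ EC-positive) to score $> t$, with $t$ chosen on held-out
scores by the Youden index $J = S + S_p - 1$; exact equality classifies as
CTRL, matching the sign convention at $t = 0$. Candidate cuts are the
midpoints between consecutive sorted unique scores plus $\pm\infty$, which
makes the choice invariant to monotone rescaling of the scores; ties in $J$
break toward higher specificity (a screening test should not inflate false
positives), then toward the higher cut. The AUC and its 95% CI use DeLong's
structural-components estimator, with the interval formed on the logit-AUC
scale and back-transformed so it respects $[0,1]$ without truncation at
moderate sample sizes.

## Base classifiers and their confidence

The seven families are concretized with standard R learners behind a uniform
(label, confidence) contract: Gaussian Naive Bayes (`e1071`), ridge-penalized
logistic regression (`glmnet`; "GLM"), a linear support-vector classifier
with Platt-calibrated probabilities (`e1071`; "fast large margin"), a small
feed-forward network (`nnet`; "deep learning" at desk scale — cohorts of
hundreds of samples and ~250 features do not support deeper architectures),
CART (`rpart`), random forest (`randomForest`), and PLS-DA implemented in the
package (NIPALS PLS1 on a 0/1 class indicator).

For probabilistic kinds the confidence is $2\,|p(\mathrm{EC}) - 0.5|$. For
PLS-DA, whose natural geometry is the latent-variable space, it is
$|d_{\mathrm{CTRL}} - d_{\mathrm{EC}}|/(d_{\mathrm{CTRL}} + d_{\mathrm{EC}})$
with $d$ the euclidean distance to each class centroid; both maps are 0 at
the boundary, 1 at certainty, and invariant to relabelling the classes.

Hyperparameters are tuned by exhaustive grid search over small default grids
(ridge penalty; margin cost; network width and weight decay; tree depth;
`mtry`; latent-variable count), scored by stratified k-fold CV accuracy
(default 10 folds; the end-to-end driver uses 5), ties to the first grid
point. Admission to the ensemble requires CV accuracy $> 0.65$ **and** CV AUC
$> 0.85$ (both strict), plus a no-overfitting guard — the verbal criterion
"no overfitting" is operationalized as training accuracy minus CV accuracy
below 0.15, a deliberately loose gap that only rejects models memorizing
their training set.

## PLS-DA diagnostics

The latent-variable count is chosen by maximum CV classification accuracy
(nearest class centroid), ties to the smaller count (parsimony). VIP scores
use the standard formula
$\mathrm{VIP}_j = \sqrt{p \sum_a \mathrm{SSY}_a w_{ja}^2 / \sum_a \mathrm{SSY}_a}$
with normalized weights, so the mean squared VIP over features is exactly 1 —
an identity the tests assert to $10^{-6}$. $R^2$ is the in-sample fraction of
class-indicator variance explained; $Q^2$ its k-fold cross-validated
analogue; the permutation test refits the model on permuted labels and
reports $p = (1 + \#\{Q^2_{\mathrm{perm}} \ge Q^2_{\mathrm{obs}}\})/(1 + n)$,
which is never exactly zero and is uniform on its grid under the null (a
property the acceptance suite checks by a KS test across seeded null runs).

## Batch quality control

Analytical batches of 25 samples carry four control injections. The two
conditions whose published wording is ambiguous are operationalized as:

* **Duplicate injection (< 15%).** "Variance among the peak areas … less than
  15% of the first injection" is read as the *mean*, over the 100 highest
  peaks of the duplicated sample, of the relative deviation
  $|q_{\mathrm{rep}} - q_{\mathrm{orig}}|/q_{\mathrm{orig}}$ of the
  IS-normalized areas; the per-peak maximum is also reported so a stricter
  per-peak reading remains auditable.
* **Pooled injection (< 5%).** "Assigned in the same area as the other pooled
  samples, i.e. < 5% of the total area of a model" is operationalized without
  refitting an unsupervised model: the euclidean distance of the batch's
  IS-normalized pooled profile from the running centroid of the *prior*
  batches' pooled profiles, divided by the euclidean norm of the per-feature
  standard deviations of all member samples (the data's total spread), must
  be below 0.05. Using only prior batches keeps the monitor causal and makes
  an outlying pooled injection flag its own batch rather than its neighbours;
  the first batch has nothing to deviate from and passes vacuously.

The blank's "no peaks" uses a detection floor of zero: any strictly positive
area is a peak, since the generator encodes absence as zero or missing. The
"very low-intensity peaks not investigated further" rule has no numeric
cutoff of record and is folded into the presence filter plus an optional
minimum-median-area threshold (off by default).

## Preprocessing

The pipeline order is fixed: IS-normalization → natural log → autoscaling.
The log base is immaterial (any fixed base differs by a constant factor that
autoscaling removes) and is fixed at $e$ for reproducibility; the autoscale
standard deviation uses the $n-1$ denominator. Transform parameters are
fitted on the training split only and frozen — fitting on all data would leak
the held-out samples' distribution into the transform. Features constant on
the training split are dropped with a warning.

Missing cells are imputed only after the 80% presence filter, by half the
feature's minimum observed value (a below-detection-limit surrogate;
per-feature median is the alternative). The screening step's
missing-data exclusion remains in force for any matrix that reaches it
unimputed: with cell-wise missingness at cohort scale, excluding every
feature containing a missing value would discard the entire table, so the
pipeline reserves that rule for the feature-screen contract and relies on
presence filtering plus imputation, documented here as a deliberate
deviation from a literal reading.

## Feature screening and the GA wrapper

The correlation screen excludes features whose point-biserial correlation
with the class is $\ge 0.95$ in magnitude (suspected leakage — nothing
biological mirrors a diagnosis that closely) or $\le 0.05$ (uninformative); the
stability screen excludes features with more than 80% identical values; both
bounds are parameters, since the source analysis quantifies neither.
Exclusion reasons are single-valued in the order correlation → stability →
missing.

The GA evolves binary feature masks by tournament selection (size 2), uniform
crossover (rate 0.8), per-bit mutation (0.02), and elitism (2), fitness =
mean stratified CV accuracy of a stated model kind at default
hyperparameters. None of these values are published; the defaults are common
GA practice and all are exposed in `ga_config()`. The end-to-end driver runs
one *shared* GA (logistic-regression fitness, population 20, 10 generations,
3-fold CV) whose subset all seven models reuse; a per-model mode matching the
stricter reading ("before each classification model") is available at about
seven times the cost, and on a shared screened matrix the per-model searches
converge to near-identical subsets.

## The synthetic cohort

`generate_cohort()` emulates what the analysis assumes about real serum
GC-MS data: 251 retained signals; log-normal peak areas (per-feature log-mean
spread 1.0 around log(2e5), log-sd 0.3–0.6, i.e. features spanning roughly
two decades of abundance with 30–60% biological CV); an internal standard
with 5% injection variation; completely-at-random missing cells (2% by
default — the real missingness mechanism is unpublished, so the simplest one
is used); and a planted 12-metabolite signature applied multiplicatively on
the raw scale, fold change 3 for the three metabolites raised in EC and 1/3
for the nine lowered, so the generator's "fold change" is exactly the
volcano's definition (ratio of geometric means). The magnitudes 3 and 1/3
are the study conditions of the end-to-end checks: clearly beyond the
volcano's 2-fold bound without being degenerate. Batches reuse a single
cohort-level pooled profile (the mean of 50 randomly selected samples)
re-injected with 0.5% noise, matching the physical reality of one pooled
solution; re-pooling per batch would violate the 5% pooled tolerance by
construction.

What the generator does **not** emulate: retention-time structure, co-eluting
peaks and derivatization multiplets, batch drift and instrument response
changes, correlated metabolite panels (features are independent given class),
non-random missingness tied to abundance, and covariate structure (age, BMI,
comorbidities). Consequently, a passing end-to-end suite shows the pipeline's
machinery is correct and calibrated under its own assumptions — it does not
certify performance on real sera, where correlated features and confounders
make both screening and classification harder.

## Problem sizes and numerical choices

The test and acceptance suites run at desk scale, chosen as the smallest
sizes at which the checked properties are stable: 200 samples per arm for the
planted-signature recovery (at that size every planted log-fold-change is
estimated to within a few percent and the volcano partition is exact with
margin); 20-seed null batteries for admission calibration; 99-permutation
tests across 40 seeds for p-value uniformity. Degenerate inputs are handled
explicitly: a non-positive internal-standard area is a hard error naming the
sample; constant features are dropped at autoscaling; a NIPALS step that
finds no residual covariance stops extracting components; strict
fold-change bounds are compared after rounding to 12 significant digits so a
fold change sitting exactly on a bound is not flagged by log/exp roundoff;
likelihood ratios with zero denominators are reported as "ND" rather than
infinities.

## Known limitations

* The published cohort-specific numbers (threshold 210 on the real
  validation set, AUC 0.974, per-class error rates) depend on private sera
  and are deliberately out of scope; the pipeline echoes their *structure*
  (score distributions, Youden cut, metric panel) on synthetic cohorts.
* The vote scale and weight combination are reconstructed, not published;
  both are parameters.
* The GA's fitness is CV accuracy inside the training split; like any
  wrapper selection it is optimistically biased for the selected subset, so
  admission decisions use the post-selection grid-search CV, and honest
  error estimates come only from the held-out 30%.
* With a single 70:30 split, the Youden threshold is chosen on the same
  held-out set the panel is reported on; with more data a third split (as in
  a train/test/validation design) is preferable, and `choose_threshold()`
  accepts any score/label vectors to support that.
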