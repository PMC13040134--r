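---
title: "Ultrasound radiomics risk models for adnexal masses: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ultrasound radiomics risk models for adnexal masses: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`radnex` implements a complete ultrasound-radiomics workflow for
discriminating benign from malignant adnexal masses: speckle reduction,
per-ROI intensity normalization, extraction of 74 IBSI-style intensity and
texture features, statistical feature selection, classifier training with
cross-validated tuning, and a validation battery covering discrimination,
classification at clinical cutoffs, calibration, decision-curve analysis and
an attribution-based overfitting diagnostic. Because no public imaging
cohort of this kind exists, the package ships a synthetic cohort generator
that reproduces the *statistical structure* of such a study; every stage of
the pipeline is exercised and tested against it.

This vignette records the model, the tunable parameters and their defaults,
and the design decisions made where the procedure is genuinely open.

## Preprocessing

**Despeckling.** Ultrasound B-mode images carry multiplicative speckle. We
use the adaptive local Wiener (Lee) filter with a 3×3 window: per pixel, a
local mean $m$ and local variance $v$ are computed over the window, the
noise floor $\nu$ is the mean of all local variances, and the output is

$$\hat x = m + \frac{\max(v-\nu,\,0)}{\max(v,\,\nu)}\,(x - m).$$

Flat regions collapse to their mean; structured, high-variance regions are
left nearly untouched. Edges use symmetric (mirror) padding (any consistent
padding choice affects only border pixels). The stage order is fixed:
despeckle the full image first, then normalize within the ROI.

**Per-ROI Z-scoring.** Each ROI is standardized by its own mean and sample
standard deviation (the $n-1$ convention; the package uses it consistently
for normalization and feature scaling, while the *feature* moments below use
population moments). Z-scoring makes every downstream feature exactly
invariant to affine intensity transforms $a\,x+b$ of the raw image, which is
what removes scanner gain/offset differences; this invariance is asserted
exactly in the tests. A constant ROI cannot be normalized: it raises a typed
`degenerate_roi` error rather than returning zeros, because every texture
feature downstream would be undefined.

## Feature set

The registry holds exactly 74 features: 17 intensity statistics (population
moments, with excess kurtosis $\mu_4/\mu_2^2 - 3$; histogram entropy and
uniformity), 25 gray-level co-occurrence features, 16 run-length features
and 16 size-zone features. The six features named in the supplementary
material of studies of this design (`F.stat.kurt`, `F_cm.info.corr.2`,
`F_rlm.glnu.norm`, `F_szm.glu.norm`, …) are guaranteed present. Shape and
morphology features are deliberately absent: the input is a single 2-D
image, so they are not computable. No NGTDM family is needed to reach 74.

Open choices, fixed as follows:

* **Discretization**: fixed bin number (default `n_bins = 32`) over
  $[\min, \max]$ of the ROI Z-scores, with *right-closed* equal-width bins
  (an interior value on a bin edge falls in the lower bin; the minimum gets
  label 1, the maximum label `n_bins`). The bin count is recorded with every
  feature vector.
* **Direction aggregation**: GLCM and GLRLM matrices are built per
  direction (0°, 45°, 90°, 135°, distance 1), symmetrized (GLCM) and
  *merged* — summed over directions — before feature computation; GLSZM
  zones are 8-connected and direction-free. Merged aggregation makes all
  texture features invariant to image transposition, which the tests
  assert.
* **Run percentage** uses the merged denominator $4 N_p$ (four scanning
  directions each cover every pixel), keeping it in $[0,1]$; zone
  percentage uses $N_p$.
* **Information correlation 2** is
  $\sqrt{1-\exp(-2(\mathrm{HXY2}-\mathrm{HXY}))}$ with entropies in bits,
  guarded at 0 when $\mathrm{HXY2}<\mathrm{HXY}$; a single-cell GLCM yields
  exactly 0. The normalized gray-level non-uniformities are
  $\sum_i (\sum_j m_{ij})^2 / N^2$.

The matrix builders are written in C++ (Rcpp); their correctness is
established by exhaustive equivalence against brute-force enumeration
oracles on *every* 2-level 3×3 and 4×4 label grid (≈66k instances), plus
hand-counted examples.

## Feature selection

The primary cascade mirrors the standard radiomics recipe, fit on the
training split only:

1. **Mann–Whitney U screen**, two-tailed, per feature (exact enumeration
   when both groups have ≤ 8 cases and no ties; otherwise the normal
   approximation with tie and continuity correction).
2. **Benjamini–Hochberg** step-up adjustment at $\alpha = 0.05$.
3. **Greedy Pearson pruning**: survivors are ordered by ascending screen
   p-value (ties by registry order) and accepted iff their absolute Pearson
   correlation with every already-accepted feature is ≤ 0.6 — so of a
   correlated pair, the feature with the lower p-value survives. The
   absolute value is used because sign-flipped duplicates are equally
   redundant; Pearson correlation is unaffected by the later Z-scaling, so
   computing it on raw training features is without loss.

MRMR (greedy relevance-minus-mean-redundancy on point-biserial relevance)
and RFE (iterative elimination of the lowest-gain feature of a refit
booster) are provided as the alternates used when the primary cascade
overfits. Feature Z-scaling statistics are always estimated on the training
split and frozen; validation data never influences them.

## Models

Four classifier families are supported: penalized logistic regression
(glmnet), support-vector machines (e1071), and two tree families — gradient
boosted trees and random forests — both fit through xgboost (the forest via
its bagged `num_parallel_tree` mode). Routing both tree families through
xgboost is a deliberate design choice with two consequences that matter
here: missing CA 125 values are handled *natively* by the trees' default
directions (no imputation anywhere in the package), and exact TreeSHAP
attributions are available for the overfitting diagnostic. The non-tree
families refuse matrices containing missing values, which is why the
clinical–radiomics variant is restricted to the tree families.

Tuning is a randomized search (default 25 draws) over deliberately modest
per-algorithm grids — tree depth 2–6 (forests 4–10), learning rate
0.01–0.3, 100–600 rounds, subsampling and column sampling fractions,
log-spaced elastic-net penalties, linear/RBF kernels with log-spaced cost
and bandwidth — scored by mean AUC over a stratified 5-fold
cross-validation and refit on the full training split. AUC is the selection
metric because discrimination is the quantity every downstream comparison
uses; accuracy would be an arbitrary alternative at these prevalences. All
randomness (folds, draws) is seeded; fits use one thread, so a seed fully
determines the model.

The 70:30 stratified split allocates `round(0.30 × stratum size)` cases per
outcome stratum to validation with *round-half-up*; no rounding rule
reproduces a specific published split exactly (seeds differ), so the rule
is simply documented.

## Evaluation battery

* **AUC** via the rank/concordance identity (ties ½) — tested to coincide
  with the Mann–Whitney statistic on every input — with stratified
  percentile bootstrap CIs (default 2000 resamples, seeded).
* **DeLong** comparisons of paired AUCs via placement values; the variance
  is verified against a leave-one-out jackknife oracle.
* **Classification metrics** at the 10% clinical referral cutoff and at the
  Youden-optimal cutoff (positivity at `risk ≥ cutoff`; Youden ties break
  toward the *lowest* cutoff, favoring sensitivity, consistent with the
  triage framing). Proportion CIs use the normal approximation throughout;
  likelihood-ratio CIs use the log method.
* **Calibration**: slope from a logistic fit of outcome on `logit(risk)`,
  intercept from a logistic fit with `logit(risk)` as offset
  (underestimation ⇒ intercept > 0, too-extreme risks ⇒ slope < 1); the
  curve is a local-linear tricube smoother with bandwidth 0.3 of the
  observed risk range (no smoother is canonical; this one is simple and
  assumption-light).
* **Decision curves**: net benefit
  $TP/n - FP/n \cdot t/(1-t)$ over thresholds 1–50%, with treat-all and
  treat-none references (closed forms tested exactly).
* **Overfit_Score**: per feature, mean |TreeSHAP| on the training split
  minus mean |TreeSHAP| on validation. A feature that only does work on
  memorized training cases produces a large positive score; a constructed
  memorization scenario (coarse informative features plus a continuous
  noise feature and 20% flipped training labels) is used to demonstrate the
  diagnostic identifies the memorization channel in ≥ 8/10 seeds.
* **Manufacturer PCA**: principal components of the Z-scaled selected
  features with a per-tag overlap summary (between-centroid distance over
  within-tag spread); because per-ROI normalization removes the synthetic
  scanner gain/offset, tags overlap.

## The synthetic cohort generator

The generator defines the study conditions and is first-class, tested code.
Each case is a smooth tissue reflectivity field times fully-developed
multiplicative speckle (gamma, shape 4, mean 1 — the standard
fully-developed-speckle approximation; nothing in the emulated study
constrains the image statistics), an elliptical ROI (≥ 32 pixels), and a
manufacturer gain/offset drawn once per scanner tag. Malignant strata
receive sparse small bright foci (multiplicative, heavy right tail —
raising intensity kurtosis) plus a few larger hypoechoic patches (distinct
gray-level zones — raising gray-level non-uniformity). An earlier design
using broad additive ± blobs *lowered* kurtosis relative to the speckle
baseline and was discarded; the final construction moves exactly the
features these studies report as top predictors. Severity scales the effect
by stratum (borderline 0.6 < metastasis 1.2 < Stage III–IV 1.4, Stage I–II
= 1).

Clinical covariates: age is normal with a class-shifted mean (default +8
years at severity 1), CA 125 is log-normal with a class-shifted location
(default +1 log-unit at severity 1) and missing completely at random at 25%
— matching the emulated cohort's missingness; the class mix defaults to the
emulated histology distribution (61.3% benign, 5.5% borderline, 12.9%
Stage I–II, 15.7% Stage III–IV, 4.7% metastases). One image per case; a
single seeded RNG stream makes a cohort a pure function of its spec.

The default texture effect size (0.5) was mapped to a discrimination target
by a one-off calibration simulation — n = 2000 cohorts, the full selection
cascade, a tuned gradient-boosted radiomics-only model — whose mean
validation AUC, 0.97, is frozen as `design_auc()`. Parameter-recovery tests
train from scratch and require agreement within ±0.05.

**What the generator does not emulate**: acoustic physics (attenuation,
shadowing, refraction), realistic organ context, inter-observer
segmentation variability, or the IOTA ultrasound descriptors. The
ADNEX-style comparator therefore receives ultrasound predictors (diameter,
solid proportion, locularity, papillations, shadows, ascites) sampled
*conditionally on outcome* with clinically plausible, deliberately strong
effects. Passing tests show the pipeline's machinery is correct and its
qualitative orderings hold under the designed conditions — not that the
models would reach any particular performance on clinical images.

## The ADNEX-style comparator

The comparator implements the published model's *structure*: a multinomial
logit over five outcome classes (benign reference; borderline, Stage I,
Stage II–IV, metastatic), log transforms of the marker and size predictors,
and separate with-CA125 / without-CA125 coefficient variants, applied
per case according to marker availability. The bundled coefficient file is
a clearly labelled **synthetic stand-in** with sign-correct, realistically
scaled values: the published coefficients are not redistributed here, and
guessing them would be worse than declaring the substitution. Consequently
the calculator is tested for its structural contracts — probabilities on
the simplex, monotonicity of the malignancy risk in each predictor's
documented direction, variant behavior — never against published risk
values. Replace `inst/extdata/adnex_coefficients_synthetic.json` with a
transcription of the published coefficients to obtain the real calculator;
the code reads any file with the same schema.

## Problem sizes and numerical choices

The test suite exercises: exhaustive 3×3/4×4 oracle equivalence (≈66k
grids); null-calibration of the screen at n = 1000; calibration recovery at
n = 10⁴; parameter recovery at n = 2000 (one cohort); ordering and
overfitting checks over 10 seeds at n = 400 and n = 300 respectively; and
pipeline smoke/determinism runs at n = 120. These sizes were chosen so the
whole suite runs comfortably on a single CPU while keeping Monte-Carlo
error well inside the asserted tolerances. The acceptance script runs the
full pipeline at n = 600 with 15 search draws per algorithm.

Numerical guards worth knowing: degenerate ROIs error (never silent zeros);
GLCM correlation is defined as 1 for a single-level matrix; information
correlation 1 is 0 when the marginal entropy vanishes; risks are clipped to
$[10^{-6}, 1-10^{-6}]$ before logits in calibration; zero-variance features
are excluded from pruning with a warning and refuse scaling with an error.

## Known limitations

* Synthetic realism is limited to "moves the right features"; no claim of
  acoustic fidelity.
* The bundled ADNEX-style coefficients are synthetic (see above).
* SVM probability estimates come from libsvm's internal Platt scaling,
  whose internal randomization is not controlled by the R seed; exact
  rerun-determinism is therefore guaranteed for the other three families
  (the pipeline's determinism tests use the boosted-tree family).
* Single image per case; no 3-D volumes, Doppler, or shape features.
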