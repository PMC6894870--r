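---
title: "Reconstruction-error routed risk prediction: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstruction-error routed risk prediction: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the method

Tabular health-survey cohorts for coronary heart disease (CHD) risk
scoring mix a majority of "typical" respondents with a minority whose
feature profiles are far more dispersed — extreme lipid values, unusual
combinations of age and blood pressure, and so on. A single classifier
fitted to the pooled data compromises between the two regimes. The method
implemented here attacks that with reconstruction error (RE) from deep
autoencoders, used twice:

1. **Routing.** An autoencoder (the *general* model) is trained on the
   whole training set to reproduce its input through a bottleneck. Rows
   the model reconstructs poorly — high RE — are the atypical minority.
   The training set is split at a threshold on RE, one deep neural network
   (DNN) classifier is trained on each side, and at prediction time each
   new sample is routed to the classifier of its own RE regime.
2. **Feature extraction.** A second autoencoder (the *risky* model) is
   trained on the high-risk training rows only. Its per-sample RE is small
   for rows resembling the high-risk population and larger for rows unlike
   it, so the scalar RE is appended to the 14 risk factors as a 15th
   classifier input.

### Autoencoder

Each affine layer computes `x_l = a_l(W_l x_{l-1} + b_l)`. The deep
autoencoder has six affine layers: a three-layer rectifier (relu) encoder
and a three-layer hyperbolic-tangent decoder, the output layer included.
The default widths are `14-10-7-4-7-10-14`: the architecture fixes depth
and activations but not widths, so the package defaults to a symmetric
taper that mirrors the classifier's tapering hidden widths, with a
bottleneck of 4. Training minimises the mean squared reconstruction error
`MSE = (1/n) Σ_i (x_i − x'_i)²` by minibatch Adamax (learning rate 0.001,
batch size 32). The per-sample RE is the coordinate mean
`re_i = (1/d) Σ_j (x_ij − x̂_ij)²`. Two reductions were possible for the
RE feature — a per-coordinate residual vector or a scalar — and the
15-neuron classifier input forces the scalar; the mean (rather than the
sum) keeps it on the same scale as the training MSE.

A deliberate quirk is kept as specified: the decoder ends in tanh even
though standardized inputs routinely exceed [−1, 1], so extreme values
carry an irreducible residual. That is precisely what makes RE a useful
atypicality score here. A `linear_output` escape hatch exists in
`ae_spec()` but is off by default.

### Threshold and partition

The splitting threshold is `mean(re) + dispersion(re)` over the training
REs. The construction is stated in terms of the mean and standard
deviation, while its printed algebra reads as mean plus *variance*; the
package defaults to the standard-deviation reading (the stated intent,
and dimensionally consistent — both terms are squared-residual
quantities) and exposes `convention = "variance"` for the literal
reading. All moments use the population (1/n) convention throughout the
package, matching the 1/n convention of the training objective; at
cohort sizes in the thousands the difference from 1/(n−1) is immaterial,
but a single fixed convention makes exact unit tests possible.
"Exceeds" is strict: a row whose RE equals the threshold goes to the
low-RE group.

### Classifier

Each DNN is `15-10-7-5-3-1`: four rectifier hidden layers and a logistic
sigmoid output. The default loss is mean squared error on the sigmoid
output — unusual for classification, but it is the stated training
objective of the method; cross-entropy is available via `dnn_spec()`. The
decision cutoff is 0.5 by default (the method statement is silent;
configurable). The RE feature is standardized jointly with the other 14
columns before entering the DNNs: raw REs are orders of magnitude smaller
than z-scores and would otherwise be washed out. Whether the two
autoencoders should share hyperparameters is unspecified; both default to
the same `ae_spec()`.

All fitted components — both standardizers, both backends, the threshold
and both DNNs — are fit strictly inside the training portion and refit
per cross-validation fold, so nothing leaks from held-out rows.

### Evaluation

`roc_auc()` computes the Mann–Whitney pair-win fraction (ties half);
`hanley_mcneil()` provides the closed-form SE, a two-sided z-test against
AUC = 0.5 (sidedness is a package choice), and a 95% CI. Mean ROC curves
are vertical averages of per-fold curves on a fixed 101-point FPR grid
(the averaging recipe is a package choice; no recipe was stated).
Positive class is high risk everywhere; the one prose sentence describing
specificity the other way round contradicts the standard confusion
arithmetic and is resolved in favour of the standard definition.
Comparators (naive Bayes, k-nearest neighbours, decision tree, random
forest, SVM) delegate to e1071, class, rpart and randomForest; their
defaults are the tuned settings reported for the original comparison
(k = 19, 110 trees, gini, radial kernel) and are arguments, not searches.

## The synthetic cohort generator

No cohort data ships with the package; `generate_cohort()` emulates the
published per-class marginal summaries of the 14 selected risk factors of
the KNHANES V–VI extract (13,075 low-risk and 12,915 high-risk records):
per-class means/SDs for the 7 continuous features and per-class category
counts for the 7 coded categorical features, counts normalised to
probabilities by their column sums. (One printed categorical column sums
to 13,064 rather than the class size; normalising by the column sum keeps
every probability vector exact.)

Design choices, in the generator's own right:

* **Independent marginals.** Only marginal summaries are published, so
  continuous features are independent truncated normals per class and
  categoricals independent multinomials. Real risk factors are correlated
  (BMI with waist circumference, age with marital status); passing tests
  on this generator demonstrates that the machinery works on data with
  class-conditional distributional structure, not that it attains any
  particular performance on real survey data.
* **Symmetric truncation.** Continuous draws are truncated to
  `mean ± min(4·sd, mean)`. Truncating asymmetrically at zero would
  preserve nonnegativity but bias the sample mean upward — by roughly a
  quarter of a year of age and several mg/dL of triglyceride for the
  most skewed features — which would defeat mean-fidelity checks;
  symmetric truncation preserves the published means exactly at the cost
  of a slightly reduced SD for features whose mean is within 4 SDs of
  zero.
* **Disorder flags.** The label is defined as the OR of six disorder
  flags (hypertension, dyslipidemia, stroke, myocardial infarction,
  angina, hyperlipidemia). How flags arise is not specified, so they are
  drawn from a logistic link on the standardized continuous features with
  plausible loadings (blood pressure into hypertension, lipids into the
  lipid disorders, age into the ischemic events) and then overridden to
  keep the label equal to the generating class. The link exists to make
  labels learnable from features, not to model epidemiology.
* **Planted anomaly subgroup.** A fraction (default 0.15) of rows in
  *both* classes has its continuous features redrawn with SDs multiplied
  by 4. This is the "higher-variance subset" that motivates RE-based
  partitioning; without it the split finds little structure (the package's
  no-signal control sets `anomaly_fraction = 0`).
* **Rare levels.** Categories with printed counts as small as 2 ("No
  response") are kept with their tiny probabilities by default;
  `min_level_count` can drop them.

## Problem sizes and profiles

The published training profile (5000 epochs) is available by argument;
the package defaults to a desk-scale profile of 200 epochs, which the
compiled Adamax trainer fits in a few seconds per network at n ≈ 5,000.
The test suite exercises the full pipeline at n = 5,000 with 10-fold
cross-validation and a three-rung ablation (single DNN on 14 features;
routed DNNs on 14; routed DNNs on 15) over 5 seeds at 3 folds.
Feature-ranking accuracies are cross-validated means under a fixed seed
rather than a single split (less noisy; a `single_split` mode exists for
fidelity), with rank ties broken by canonical feature order.

## Numerical and degenerate-input choices

* Categorical codes enter the classifiers as ordinal numerics — the
  15-neuron input forbids one-hot expansion — including the 8/9/88
  special codes at their face values.
* Constant columns are rejected by the standardizer with an error naming
  the column; missing values are rejected, not imputed.
* A partition group lacking rows of both classes aborts the fit with an
  error suggesting the other threshold convention; a training set with a
  single class aborts; a single-class group inside `fit_dnn()` warns and
  fits a constant-tending model.
* Every stochastic stage consumes a sub-seed derived from one master
  seed; fits are bit-reproducible on a fixed BLAS/thread configuration,
  and bundles serialize numerics as `%.17g` text so save/load round-trips
  and same-seed refits are byte-identical.
* Degenerate AUC ∈ {0, 1} gives SE 0; the z statistic is reported as
  signed infinity with p = 0.

## Known limitations

* The generator reproduces marginal structure only; covariance,
  survey-design weights and missing-data patterns of the real survey are
  out of scope (a covariance hook would slot into `.draw_class()`).
* Reported performance on synthetic cohorts is not comparable to
  performance on the real survey extract, which is not redistributable
  here.
* No probability calibration, no hyperparameter search, and no
  DeLong/bootstrap AUC comparisons — the Hanley–McNeil closed form only.
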