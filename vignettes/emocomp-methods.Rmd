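---
title: "Methods: emotion classification and organizational competitiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: emotion classification and organizational competitiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

`emocomp` models a two-stage workplace-affect analysis. Stage one
classifies the emotional state of individual employees — neutral, happy,
excited or angry — from a tabular record of physiological and
demographic measurements: blood volume pulse (BVP), galvanic skin
response (GSR), skin temperature (SKT), self-reported valence and
arousal on the circumplex model of affect, plus age, gender, height,
weight and body mass index. Stage two aggregates the predicted emotions
of each organization's employees into an emotion-fraction profile and
categorizes the organization's competitiveness as high, moderate or low:
happy/excited-dominated workforces indicate high competitiveness,
neutral-dominated moderate, and angry-dominated low. Organizational rank
(1–10) provides an independent, a-priori competitiveness label
(1–5 high, 6–8 moderate, 9–10 low) against which the emotion-derived
categorization can be audited.

# The synthetic study population

No real sensor recordings are distributed; instead `simulate_employees()`
generates a population that reproduces the published statistical
structure of the study cohort:

* 1200 employees across 10 organizations with a fixed rank distribution
  (130, 131, 121, 127, 123, 135, 100, 125, 110, 98 employees on ranks
  1–10) and 52.2% male.
* Four emotion classes with fixed counts (320 neutral, 349 happy,
  295 excited, 236 angry), allocated by deterministic largest-remainder
  rounding so the counts are exact at any generated size.
* Within each class, the seven modeled features
  (age, BMI, BVP, GSR, SKT, valence, arousal) follow a multivariate
  Gaussian whose mean and SD vectors are the published per-class values
  and whose correlation matrix carries all 21 published pairwise Pearson
  correlations for that class.

Only marginal moments and pairwise correlations of the cohort are
published, so a Gaussian copula-style joint model is the minimal
assumption that reproduces all of them; any non-Gaussian tail behavior
of the real signals is *not* emulated, and passing tests consequently
say nothing about heavy tails, missingness, sensor drift or temporal
dynamics of real recordings.

Because a set of printed pairwise correlations need not form a valid
joint correlation matrix, every class matrix passes through
`nearest_psd()`, a Higham-style alternating projection (eigenvalue
clipping with diagonal restoration). For these parameters all four
matrices are already positive-definite (smallest eigenvalue 0.059, in
the neutral class), so the projection leaves them unchanged and the
"PSD-corrected targets" used in tests coincide with the printed values.

Height is not published per class; it is drawn as Gaussian
(170 cm, SD 10) and weight is back-derived as `BMI * (height/100)^2` so
the BMI/weight/height identity holds exactly in every record.

## Plausibility clipping

Sampled features are clipped to configurable plausibility ranges. The
defaults are deliberately wide — age [0, 100], valence/arousal [0, 10],
GSR ≥ 0, SKT [20, 40] °C, BMI [10, 60] — because clipping is a
winsorization and biases the recovered moments wherever a bound sits
within a few SDs of a class mean. Tighter, superficially natural bounds
(working age ≥ 18, affect scale ≥ 1) would bias the angry-class age mean
by ≈ +0.32 y and the angry-class valence mean by ≈ +0.013, both larger
than the package's own moment-recovery tolerance of `3·SD/sqrt(n)` at
n = 20000. With the wide defaults the clipping probability is below
0.3% in every feature–class combination and the bias is negligible
(≤ 0.02 SD). The guards exist to keep jittered augmentation from
producing physically impossible values, not to shape distributions.

## Augmentation

The published experiment augments the 1200-record cohort to "around
5000"; the mechanism is not described. `augment_records()` uses jittered
resampling: added records are drawn per class with replacement and each
modeled feature receives Gaussian noise with SD equal to
`noise_scale = 0.05` of the class's empirical feature SD. This preserves
class proportions to within one record (largest-remainder allocation),
leaves class moments essentially unchanged at the 0.05 scale, and gives
the classifier the enlarged training set the published pipeline used.
`noise_scale = 0` duplicates records exactly.

## The 13 input nodes

The published input layer has 13 nodes while the data dictionary lists
12 columns; the encoding chosen here is
`(org_rank, gender_male, gender_female, age, height, weight, bmi, bvp,
gsr, skt, valence, arousal, subject_index_scaled)` — one-hot gender
(2 dims) plus a scaled subject index reconcile the count. Every column
is standardized to zero mean/unit variance (constant columns set to 0).
The subject index is an identifier surrogate with no biological meaning;
on generated data its blockwise correlation with class can make it
weakly informative inside cross-validation, which mirrors what a real
pipeline feeding an ID-derived column into a network would do.

# The 1D convolutional network

The classifier is written from scratch in the package (no deep-learning
framework): `depth` convolutional groups (1D convolution + ELU +
average pooling by factor `tt`), a fully connected ELU hidden layer, and
a linear 4-score output. Forward propagation in a convolutional layer is

    y_l = C_l + sum_j conv1d(x_jl, t_j),   z_l = f(y_l),   t_l = z_l ↓ tt

with ELU activation `f`. The loss for one record is the sum of squared
differences between the 4 output scores and the one-hot target — not
cross-entropy, by design fidelity to the source method. Backpropagation
is hand-derived: the delta error enters a convolutional layer through a
full (zero-padded) convolution with the reversed kernels, pooling is
inverted by zero-order upsampling scaled by `1/tt` (the exact adjoint of
average pooling — see the inner-product tests), and kernel gradients are
valid convolutions of the layer input with the downstream delta. The
entire analytic gradient is verified against central finite differences
(relative error < 1e-4) across padding modes and pool factors.

Implementation note: batches are processed as im2col matrices so the
training loop runs in BLAS matrix products; one mini-batch step applies
the *summed* per-sample gradients, so batch size 1 reduces exactly to
per-presentation SGD with learning factor ε.

## Choices the source method leaves open

* **Padding.** Valid convolution with depth 5 and kernel 7 is impossible
  on a 13-length input (the signal would shrink away), so convolutional
  groups use `same` zero padding by default; `valid` mode remains
  available and the constructor proves feasibility of any configuration
  before training.
* **Pooling.** The published backward pass upsamples by zero order,
  which is the adjoint of average pooling, so pooling is average;
  `tt = 1` by default because a 13-length signal leaves no room to pool
  (pooling is skipped whenever the signal is shorter than `2·tt`).
* **Width.** Filters per group (16) and hidden width (32) are not
  published ("fewer than 50 neurons" is the only hint); the defaults are
  the smallest round sizes that train to the headline accuracy reliably.
* **Initialization.** Scaled-uniform (±sqrt(6/(fan_in+fan_out))),
  seeded; training is bitwise reproducible on one thread under a fixed
  seed.
* **Epochs.** Default 100 with mini-batches of 32 and early stopping on
  a loss plateau (relative change < 1e-6 over 20 epochs). On the default
  synthetic cohort the loss plateaus well inside this budget; the cap
  mainly bounds the cost of the 5-fold cross-validation, which processes
  5 × 4000 training records per run.
* **Cross-validation.** Stratified 5-fold (the source states only
  "cross-validation"); folds are seeded and shared with the comparator
  baselines so every model sees identical partitions.
* **Prediction ties.** `argmax` with lowest-class-index tie-breaking.

The published hyperparameter study (16 configurations: depth 3–6 ×
kernel 3/5/7/9 with associated learning rates, all ELU) is available as
`odcnn_reference_grid()`; configuration 11 — depth 5, kernel 7, learning
rate 0.0005 — is the published optimum and the package default.

# Evaluation statistics

One-way ANOVA (equal-variance F test) and Pearson correlations with
t-transform p values reproduce the published per-feature comparisons on
generated cohorts: BVP, GSR, SKT, valence and arousal separate the
emotion groups at p < 0.01 while BMI does not (p ≈ 0.5), matching the
published pattern. Classifier evaluation uses the pooled held-out
confusion matrix, accuracy, and one-vs-rest ROC AUC per class computed
by the midrank (Mann–Whitney) method — equivalent to trapezoidal ROC
integration with midrank ties — macro-averaged without weights (the
averaging scheme behind the single published AUC is unstated). A class
absent from the truth vector yields an undefined AUC, is flagged `NA`,
and is excluded from the macro average.

Two comparator baselines run under the same folds: a one-vs-rest
Gaussian-kernel SVM with kernel scale 2.5 (`gamma = 1/2.5²`, via e1071)
and a RUSBoost-style ensemble of 20 shallow decision trees (rpart
learners capped near 30 splits via depth, SAMME weighting, random
per-class undersampling each round). Their *published* accuracies
(83.5%, 71.4%) are properties of the unavailable real dataset and are
not reproduction targets: the synthetic cohort is separable by
construction, so comparators score far higher here, and the package
makes no claim otherwise.

# The self-organizing map

Stage two feeds per-organization emotion-fraction profiles (4-vectors)
to a Kohonen map on a rectangular `rows × cols` lattice. Each
presentation finds the best matching unit by Euclidean distance
(ties: smallest row-major index) and updates every node by

    x_ij(t+1) = x_ij(t) + β(t) · γ_ij(t) · (y(t) − x_ij(t))

with exponentially decaying learning rate `β(t) = β0·exp(−t/λ)` and
radius `α(t) = α0·exp(−t/λ)`, and Gaussian neighborhood
`γ_ij = exp(−e²/(2α(t)²))` on integer lattice coordinates. The
neighborhood-weighted update (rather than the plain BMU-only variant) is
the default as the more precise rule; no hard radius cutoff is applied
because γ is already negligible beyond α. Defaults follow standard
Kohonen heuristics: 10 × 10 lattice, `α0 = max(rows, cols)/2`,
`β0 = 0.5`, budget `o = 1000 ×` number of inputs, `λ = o / log(α0)`.
Because each update is a convex combination, weights remain in the hull
of the data, and the per-epoch quantization error is recorded as the fit
diagnostic.

Whether the published map consumes employees or organizations is
ambiguous; the package's primary mode consumes organization profiles
(matching the stated goal of clustering overall organizational
emotions), and the CLI exposes a per-employee mode (one-hot emotion +
scaled rank) behind `--mode employee`. The trained codebook is
partitioned by K-means with k = 4 (seeded, 20 restarts, best
within-cluster sum of squares kept; delegated to `stats::kmeans`), and
each cluster centroid's dominant emotion determines the category of its
member organizations — ties resolved pessimistically
(angry > neutral > happy > excited).

# Numerical and reproducibility choices

* Every stochastic operation accepts a seed; the pipeline derives
  per-stage seeds from one master seed by a fixed affine map modulo
  2³¹ − 1, so stages are independently reproducible and a rerun with the
  same configuration produces byte-identical artifacts (verified by MD5
  manifests).
* `nearest_psd` guarantees minimum eigenvalue ≥ −1e−10 and returns
  already-PSD inputs unchanged.
* Degenerate inputs are rejected with informative errors: infeasible
  depth/kernel combinations, non-finite gradients (divergence reports
  the epoch), classes with fewer members than folds, empty profile sets,
  ranks outside 1–10.
* Problem sizes in the test suite are chosen to keep the full run modest
  on a single CPU: the headline 5-fold cross-validation runs once on the
  full 5000-record cohort, property checks use small architectures and
  20 000-record single-class samples, and the end-to-end pipeline test
  runs a 200 → 400-record configuration.

# Known limitations

* The generator reproduces first and second moments only; all
  higher-order structure is Gaussian by assumption.
* The synthetic classes are separable by construction (e.g. happy vs
  neutral GSR: 6.19 ± 0.05 vs 4.95 ± 0.07), so near-perfect classifier
  accuracy here demonstrates the training machinery, not real-world
  emotion-recognition difficulty, and comparator rankings need not
  transfer to real recordings.
* The per-layer filter counts behind the published configuration study
  are unknown; the defaults are assumptions, and accuracy differences
  between grid rows on synthetic data are small and seed-dependent.
* Timing/throughput figures of the published tables are
  hardware-dependent and out of scope.
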