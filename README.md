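# emocomp

Classification of employee emotional states from physiological signals,
and categorization of organizational competitiveness from the emotions
of each organization's workforce.

## What it does

**Stage 1 — emotion classification.** Each employee record carries
demographics (age, gender, height, weight, BMI), physiological
measurements (blood volume pulse, galvanic skin response, skin
temperature) and circumplex affect scores (valence, arousal), with an
emotional-state label in {neutral, happy, excited, angry}. A
one-dimensional convolutional neural network — implemented from scratch
in this package, including its hand-derived backpropagation — maps the
13-feature input to 4 class scores. Forward propagation per
convolutional layer is

    y_l = C_l + Σ_j conv1d(x_jl, t_j),   z_l = ELU(y_l),   t_l = z_l ↓ tt

trained by stochastic gradient descent (`w ← w − ε ∂F/∂w`) on the
sum-of-squares loss `F = Σ_j (z_j − u_j)²` against one-hot targets.
The reference configuration is depth 5, kernel size 7, ε = 0.0005, ELU.

**Stage 2 — organizational competitiveness.** Predicted emotions are
aggregated into one emotion-fraction profile per organization, a Kohonen
self-organizing map is trained on the profiles
(`x_ij(t+1) = x_ij(t) + β(t) γ_ij(t) (y(t) − x_ij(t))`, with
exponentially decaying learning rate and Gaussian neighborhood), its
codebook is partitioned by K-means into four clusters, and each
cluster's dominant emotion yields the category: happy/excited → high,
neutral → moderate, angry → low. Organizational rank (1–5 high, 6–8
moderate, 9–10 low) provides an independent label for auditing.

Because no study data are deposited, the package ships a seeded
generator that reproduces the study population's printed structure:
per-class feature means/SDs and full pairwise correlation matrices
(projected to the nearest positive-semidefinite correlation matrix when
needed), class counts (320/349/295/236 at n = 1200), the 10-rank
organization distribution, 52.2% male, and jittered-resampling
augmentation to 5000 records.

## Worked example

```r
library(emocomp)

cfg <- emotion_sim_config(n_base = 300, n_augmented = 600, seed = 42)
d   <- simulate_employees(cfg)                  # 300 records, 4 classes
d5  <- augment_records(d, 600, seed = 43)       # jittered resampling
fm  <- emotion_feature_matrix(d5)               # 13 standardized features

cv <- cv_odcnn(fm$x, fm$y, odcnn_config(depth = 3, epochs = 40, seed = 44),
               k = 3)
print(cv)
#> ODCNN cross-validated report
#>   accuracy: 0.9950 (3 misclassified)
#>   macro one-vs-rest AUC: 0.9998
#>   confusion (rows = truth):
#>          predicted
#> truth     neutral happy excited angry
#>   neutral     160     0       0     0
#>   happy         0   174       0     0
#>   excited       0     0     148     0
#>   angry         3     0       0   115

fit   <- odcnn(fm$x, fm$y, odcnn_config(depth = 3, epochs = 40, seed = 44))
profs <- org_profiles(d5$org_rank, emotion_levels()[predict(fit, fm$x) + 1L])
som   <- som_fit(as.matrix(profs[, emotion_levels()]), rows = 6, cols = 6,
                 iterations = 10000, seed = 45)
rep   <- categorize_competitiveness(profs, som,
                                    kmeans_partition(som, 4, seed = 46))
rep[, c("org_rank", "n_employees", "dominant", "category")]
#>    org_rank n_employees dominant category
#> 1         1          60  neutral moderate
#> 2         2          79    happy     high
#> 3         3          61    angry      low
#> 4         4          68    happy     high
#> ...
```

The cross-validated accuracy (99.5% on this scaled-down run; 99.8–99.9%
at the full 1200 → 5000 default) is the pooled held-out accuracy over
stratified folds, and the macro AUC is the unweighted mean of the four
one-vs-rest ROC AUCs. In the competitiveness table each organization is
assigned the category of its SOM codebook cluster's dominant emotion;
note that the default generator assigns ranks independently of
emotions, so rank and emotion-derived category agree only when the
population is constructed rank-consistently (see the test suite's
end-to-end check).

A command-line interface wrapping the same functions is installed at
`inst/cli/emocomp.R` with subcommands
`generate | train | cv | grid | predict | som | report | all`.

## Package layout

| Where | What |
|---|---|
| `R/class-stats.R`, `R/datagen.R` | study parameterization, PSD projection, generator, augmentation, feature encoding |
| `R/odcnn-ops.R`, `R/odcnn.R`, `R/odcnn-cv.R` | convolution/pooling/ELU primitives, the network, training, CV, the 16-configuration grid |
| `R/som.R` | Kohonen map, K-means codebook partition, competitiveness categorization |
| `R/evalstats.R` | ANOVA, Pearson correlation, confusion/AUC, SVM and RUSBoost comparators |
| `R/pipeline.R`, `inst/cli/emocomp.R` | end-to-end pipeline with manifests, CLI |
| `vignettes/emocomp-methods.Rmd` | the model, assumptions, design choices and limitations |
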