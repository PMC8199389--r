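Package: emocomp
Title: Emotion Classification and Organizational Competitiveness from
    Physiological Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage pipeline that classifies employee emotional states
    (neutral, happy, excited, angry) from tabular physiological and
    demographic features -- blood volume pulse, galvanic skin response,
    skin temperature, valence, arousal, age, and body mass index -- with a
    from-scratch one-dimensional convolutional neural network trained by
    hand-derived backpropagation, and then categorizes the competitiveness
    of whole organizations (high, moderate, low) by clustering aggregated
    per-organization emotion profiles with a Kohonen self-organizing map
    whose codebook is partitioned by K-means.  Includes a seeded synthetic
    data generator that reproduces the study population's per-class
    moments, correlation structure, demographics and augmentation, plus
    evaluation statistics (one-way ANOVA, Pearson correlation, confusion
    matrices, one-vs-rest ROC/AUC) and comparator baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml,
    e1071,
    rpart
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    pROC,
    optparse
Config/testthat/edition: 3
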