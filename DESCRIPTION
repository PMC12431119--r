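Package: enosefl
Title: Fuzzy-Logic Classification of Hybrid Electronic-Nose Breath Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of hybrid electronic-nose breath
    experiments combining metal-oxide-semiconductor (MOS) and quartz crystal
    microbalance (QCM) gas sensor arrays for three-class breath screening
    (lung cancer, healthy non-smoker, healthy smoker). Provides a synthetic
    breath-signal generator with first-order sensor kinetics, preprocessing
    utilities (reference correction, voltage-to-conductance conversion,
    Sauerbrey mass sensitivity, dissipation), time-series feature extraction
    into MOS (91), QCM (7) and hybrid (98) column feature matrices, PCA and
    Fisher linear-discriminant projection, a Mamdani-style fuzzy rule-base
    classifier on the two-dimensional discriminant plane, five nature-inspired
    optimizers (GA, PSO, SA, IWO, AEO) for tuning membership-function
    parameters, and a stratified repeated cross-validation harness with
    conventional machine-learning baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    pracma,
    e1071,
    rpart,
    randomForest,
    class
Suggests:
    testthat (>= 3.0.0),
    MASS,
    cluster,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
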