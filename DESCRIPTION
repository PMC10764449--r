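Package: tendonwatch
Title: Home-Cage Locomotor Activity and Tendon-Healing Histomorphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline linking home-cage locomotor
    activity of tendon-injured mice to histomorphometric tendon-healing
    outcomes. Provides a synthetic-data generator with known ground truth
    (circadian locomotion-index traces, oriented-nuclei fluorescence fields,
    correlated tendon-level metric cohorts, two-assessor ordinal rating
    tables), activity time-series metrics (light/dark means, 3-h circadian
    bins, baseline- and control-normalized night activity), image-based
    histomorphometry (nuclei detection and counting, structure-tensor
    directionality with Gaussian peak fitting, five-area spatial bookkeeping),
    an executable ordinal scoring rubric with Total Histological Score,
    inter-assessor agreement statistics (percent agreement, Cohen's kappa,
    weighted kappa), and correlation/group-comparison inference (Pearson
    matrix with Fisher Z' confidence intervals, one-way ANOVA with Tukey HSD,
    independent t-test, D'Agostino-Pearson normality).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    MASS,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
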