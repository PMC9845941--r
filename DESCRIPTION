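Package: relapsemarkers
Title: Computational and fNIRS Markers of Relapse Risk in Alcohol Use
    Disorder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for a longitudinal relapse-prognosis analysis in
    alcohol use disorder. Implements a prospect-theory model of
    risk-based gambling choice (power utility sensitivity, one-parameter
    Prelec probability weighting, softmax choice rule) with multi-start
    maximum-likelihood fitting and agent simulation; integral-mode
    processing of multichannel fNIRS oxy-hemoglobin block designs
    (moving-average smoothing, deterministic artifact-channel rejection,
    linear inter-baseline correction, per-region integral activation and
    the emotional-minus-neutral contrast); scoring of emotional
    go/no-go, n-back and verbal-fluency task logs; group comparisons,
    Spearman correlations and a standardized binomial logistic
    prognosis model with a Box-Tidwell linearity check; and a
    calibrated synthetic-cohort generator so the full pipeline is
    testable end to end without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    zoo
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'decision-model.R'
    'fnirs.R'
    'behavior.R'
    'group-stats.R'
    'synth-cohort.R'
    'pipeline.R'
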