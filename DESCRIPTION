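Package: parosim
Title: Parosmia Severity Index from Odor-Descriptor Classifications
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing patient classifications of named odor
    descriptors in qualitative olfactory disorder (parosmia). Provides
    descriptor-level affectedness statistics with normal-approximation
    confidence intervals, correlations between descriptor semantic
    variables (olfactory association and specificity indices, valence,
    arousal, modality ratings) and response percentages, random-intercept
    logistic mixed-effects models of qualitatively-different and odorless
    responses, and a PCA-weighted parosmia severity index scored per
    participant. Includes bootstrap-regression multiple imputation of
    participant covariates, two-standard-deviation predictor scaling,
    a maximin descriptor-subset selector for embedding spaces, and a
    calibrated synthetic-cohort generator so the full pipeline can be
    exercised and validated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    splines,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
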