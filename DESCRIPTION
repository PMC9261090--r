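Package: evalspace
Title: Evaluative Space Model Analysis of Affective Picture Ratings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing trial-level affective ratings (positivity,
    negativity, arousal on 0-8 scales) under the Evaluative Space Model.
    Provides the ambivalence (affect co-activation) index, questionnaire
    scoring and normalization for symptom scales (CAPE, Chapman anhedonia),
    data-quality screening (long-string careless responding, task-completion
    eligibility), construction of the activation-function dataset with a
    random per-participant neutral split, linear mixed models with crossed
    by-subject and by-stimulus random effects (REML via 'lme4', Satterthwaite
    degrees of freedom via 'lmerTest'), estimation of the positivity offset
    and negativity bias with cross-level symptom moderation and conditional
    (simple) effects, a synthetic-data generator that emulates the assumed
    rating structure, and a parameter-recovery simulation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lme4,
    lmerTest,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
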