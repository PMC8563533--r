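Package: sdqmix
Title: Multilevel Mixture Modelling of Multi-Informant SDQ Score Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies latent score profiles from paired adolescent self- and
    parent-reported Strengths and Difficulties Questionnaire (SDQ) subscale
    scores with a two-level finite mixture model (informant records nested in
    subjects, ordinal subscale indicators), selects the number of profiles by
    BIC, scores new cases from any subset of observed scores, interprets
    profiles against cutoff bands, and estimates classification-error-corrected
    profile prevalences across groups (care setting, diagnosis, gender) with a
    three-step bias-adjusted procedure. Includes a synthetic-data generator
    with known ground truth for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
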