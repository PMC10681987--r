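Package: neurolat
Title: Hemispheric Lateralization Dynamics in Songbird Auditory Electrophysiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies auditory neural responses from trial-aligned
    extracellular recordings and scores the accompanying operant behavior.
    Computes windowed root-mean-square response magnitudes (per-trial ARM for
    multi-unit activity, trial-averaged eARM for event-related potentials),
    normalized stimulus-specific adaptation rates with the NCM site-inclusion
    filter, baseline-corrected hemispheric lateralization indices binned over
    exposure time, and Go/NoGo block performance with criterion detection.
    Ships a synthetic-data generator emulating bilateral recordings with
    stimulus-specific adaptation and condition-dependent hemispheric gain,
    plus a statistical stage (factorial ANOVA, Bonferroni post-hoc t tests,
    repeated-measures ANCOVA, Kruskal-Wallis) over standard linear-model
    machinery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    generics,
    car,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
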