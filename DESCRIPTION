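Package: matingasym
Title: Quantifying Copulation-Posture and Genital Asymmetry in Drosophila
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify one-sided (left/right) mating postures and
    bilateral morphological asymmetry in Drosophila mating experiments.
    Provides event-timeline validation and copulation-duration summaries,
    landmark-based signed mating-angle measurement with two-point
    (Bookstein) registration, per-species directional contrast tests with
    Bonferroni correction, measurement-repeatability ANOVA, interval
    summaries of frontal tilt angles, a directional- versus
    fluctuating-asymmetry classifier for paired left/right structure
    lengths, and small-parsimony (Fitch/Sankoff) mapping of discrete
    sexual characters on a cladogram. A synthetic-data generator emulates
    per-species copulation-duration and mating-angle distributions,
    arbitrary camera pose, landmark noise and exclusion categories so the
    full pipeline runs end to end without video recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    multcomp,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
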