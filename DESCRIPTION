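Package: arttrigger
Title: Trigger Analysis for Daily Online Adaptive Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study when daily online adaptive radiotherapy (ART) is
    worth performing. Computes cumulative dose-volume histogram metrics
    (Dx%, Dxcc, Vx%, VxGy) from voxel dose grids and structure masks, builds
    per-fraction difference tables between the reference, scheduled and
    adapted dose distributions of a treatment course, and evaluates adaptive
    trigger parameter-value pairs in terms of the proportion of treatments
    adapted and the counterfactual distribution of dose-metric values.
    Includes a synthetic pelvic cohort generator (metric-level and voxel-level
    phantoms) for exercising trigger policies at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr,
    yaml
Config/testthat/edition: 3
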