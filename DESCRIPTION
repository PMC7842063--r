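Package: gaitdose
Title: Spatiotemporal Gait Indices and Cerebellar Electric-Field
    Dose-Response Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reproducible pipeline from instrumented-shoe gait events to
    spatiotemporal gait indices, percent-normalized pre/post change scores,
    montage comparison by exact two-sided Wilcoxon rank-sum test, and
    partial least squares regression relating cerebellar lobular electric
    field strength to gait-parameter change. Includes a synthetic cohort
    generator emulating hemiplegic two-leg gait with side-asymmetric stance
    fractions, force-sensitive-resistor trace synthesis, and plantable
    linear field-to-change associations so every stage is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
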