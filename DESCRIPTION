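Package: methylscore
Title: Cumulative DNA Methylation Scores for Prenatal Air Pollution Exposure
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for testing whether prenatal particulate-matter exposure
    leaves detectable DNA methylation signatures in childhood saliva.
    Implements inverse-distance-weighted assignment of windowed air-pollution
    exposure from monitor networks, 450k-style sample and probe quality
    control, two-cell-type (immune/epithelial) deconvolution by constrained
    projection, cumulative DNA methylation scores built from independent
    EWAS meta-analysis weights in three variants, per-visit linear and
    random-intercept mixed association models with IQR-scaled effects, and a
    calibrated synthetic-cohort generator with planted effects so the whole
    pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    geosphere,
    jsonlite,
    nlme,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
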