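Package: planscope
Title: Complexity, Quality and QA Analysis of VMAT Radiotherapy Plans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating volumetric-modulated arc therapy (VMAT)
    treatment plans for head and neck cancer. Reads DICOM RT Plan, RT Dose
    and RT Structure Set files; computes multileaf-collimator beam-complexity
    scores (leaf speed and acceleration fractions, mean field area,
    cross-axis score, closed leaf score, small aperture scores, MU per
    control point); derives dose-volume-histogram plan-quality metrics
    (conformity number, heterogeneity index, organ-at-risk dose statistics
    against a constraint protocol); performs 2D gamma-index comparison of
    dose images for patient-specific quality assurance; and compares paired
    plan cohorts with exact Wilcoxon signed-rank tests. Includes synthetic
    DICOM-RT generators with analytic ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
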