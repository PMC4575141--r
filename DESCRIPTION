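Package: crescreen
Title: Constitutive-Activity Screening Analysis for CRE-Luciferase Reporter Plates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for plate-based CRE-luciferase reporter screens
    of G protein coupled receptor constitutive activity. Implements per-plate
    normalization by the forskolin positive control, fractional
    stimulation/inhibition relative to matched empty-vector controls, a
    replicated randomized complete block ANOVA with treatment-by-block
    diagnostics, three-criterion constitutive-activity calling with five-group
    classification, a synthetic plate-data generator with known ground truth,
    operating-characteristics evaluation (false-positive rate, group recovery,
    power curves), and the published 40-receptor orphan-GPCR screen summary.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
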