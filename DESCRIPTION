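Package: cortindex
Title: Radiomic Corticalization Index Analysis of Peri-Implant Bone
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Texture analysis of peri-implant bone on intraoral radiographs.
    Computes first- and second-order radiomic features (mean optical density,
    co-occurrence difference entropy, run-length long-run emphasis) on
    intensity-normalized, 6-bit quantized regions of interest and combines
    them into the corticalization index (CI), a score that is high where
    trabecular bone has remodeled into dense, cortical-like bone. Includes a
    synthetic radiograph and longitudinal cohort simulator (clinical data of
    this kind are typically available only on request), and the cohort-level
    statistical workflow relating CI to marginal bone loss: normality-gated
    two-group and multi-group comparisons, simple regression, longitudinal
    summaries and median group tables with high/low flags.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    sp,
    stats,
    truncnorm,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
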