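Package: breathmark
Title: Breath VOC Biomarker Discovery and Weighted Digital Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for point-of-care breath volatolomics with a
    gas chromatograph / surface acoustic wave (GC-SAW) detector. Converts
    paired breath and room-air chromatograms into segmented alveolar
    gradients (breath minus room air), ranks segments as candidate disease
    biomarkers by their C-statistic (ROC AUC), calibrates the selection
    against a Monte-Carlo permutation null via correct-versus-random
    rank-abundance curves, merges adjacent-scan signals into biomarker
    peaks, fits a weighted digital analysis (WDA) classifier, validates it
    with exhaustive leave-one-out cross-validation, and projects expected
    screening outcomes (PPV/NPV, enrichment factors) onto a population.
    Includes a synthetic cohort generator with planted informative peaks so
    every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
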