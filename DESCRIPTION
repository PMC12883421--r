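Package: mpnmorph
Title: Morphometric Classification of Myeloproliferative Neoplasms from
    Bone-Marrow Histology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated morphology-based subtyping of myeloproliferative
    neoplasms (pre-PMF, PV, ET) from bone-marrow-biopsy regions of interest.
    Implements automatic cellularity computation (background-calibrated
    adipocyte detection and watershed nucleated-cell detection), nuclear
    morphometry with an eccentricity/caliper megakaryocyte filter, per-patient
    statistical feature building, Kruskal-Wallis feature screening, linear
    support-vector-machine classification with repeated stratified
    cross-validation, weighted one-vs-rest multiclass AUC and micro-averaged
    metrics, and score-based assignment of MPN-NOS cases. Ships a seeded
    synthetic bone-marrow image generator with ground-truth masks so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    e1071,
    jsonlite,
    stats,
    tibble,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
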