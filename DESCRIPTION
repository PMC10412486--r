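Package: histoConcord
Title: Interobserver Concordance of Whole-Mount Prostatectomy Annotations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies agreement between pathologists who independently
    annotate serial whole-mount radical-prostatectomy slides with polygon
    regions of Gleason patterns, mixed Gleason scores, cribriform growth /
    intraductal carcinoma, prostatitis and HGPIN. Implements surface-overlap
    concordance via an area-weighted Dice similarity coefficient pooled per
    specimen and across a cohort, per-slide categorical agreement via Fleiss
    kappa with bootstrap confidence intervals, and index-lesion localization
    and grading concordance through Gleason pattern to ISUP Grade Group
    translation. Includes exact polygon boolean-area computation with an
    independent rasterization oracle, GeoJSON annotation import/export, and
    a synthetic paired-observer cohort generator with controllable boundary
    jitter and label confusion so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'labels.R'
    'AllClasses.R'
    'geometry.R'
    'annotation-io.R'
    'grading.R'
    'concordance.R'
    'agreement.R'
    'index-lesion.R'
    'synthetic.R'
    'pipeline.R'
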