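Package: plaquebox
Title: Weak-Label Detection, Consensus Annotation and Whole-Slide
    Scoring of Amyloid Pathologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the non-neural portion of a weak-label amyloid
    pathology detection workflow on immunohistochemistry whole-slide
    images: bounding-box geometry with iterative same-class merging,
    stain-specific HSV gating and watershed-based candidate detection,
    multi-expert consensus annotation and interrater agreement
    statistics, PASCAL-VOC-style detection evaluation with pluggable
    detector and classifier interfaces, tile-wise whole-slide scoring
    with CERAD-like category statistics, and a seeded synthetic-data
    generator that stands in for slides, expert annotators, detectors
    and classifiers so every stage is testable without external image
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
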