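Package: actomotion
Title: Quantification of Actomyosin Motility Assays and Fission-Yeast
    Cytokinesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying in vitro actin gliding (surface motility)
    assays and fission-yeast cell-scale phenotypes. Provides a ground-truthed
    simulator of gliding-filament time-lapse movies, per-frame filament
    segmentation with skeleton-based length measurement, nearest-neighbour
    track linking with motility summaries (filament counts, moving fraction,
    gliding speed), and a frame-ratio change detector that scores abrupt
    filament displacement ("wobbling") and surface detachment against a
    background-derived threshold. Also implements spherocylinder cell
    morphometrics (volume and surface area from length/width of septated
    cells) and cytokinetic-ring phase timing (node coalescence, dwell,
    constriction) with per-strain summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    png,
    stats,
    tiff,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
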