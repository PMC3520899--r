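Package: titerscreen
Title: Analysis of Arrayed Lentiviral Library Titer Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of arrayed lentiviral overexpression
    library screens run in 96-well plates. Normalizes plate-reader GFP
    fluorescence of virus-producing wells against mock-transfection
    controls, classifies per-well viral titer against control-derived
    thresholds (detection at two mock standard deviations, sufficiency at
    the empty-vector minimum, high/low tails, DNA-concentration
    exclusion), quantifies transduction rates from two-channel
    high-content images by nuclear segmentation and per-nucleus marker
    scoring, counts live/dead objects in three-channel Hoechst/PI/GFP
    assays, and compares low- versus high-titer gene groups with the
    Aspin-Welch unequal-variance test. Includes seeded synthetic-data
    generators for plates and well images with recorded ground truth so
    the whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    stats,
    tiff,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
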