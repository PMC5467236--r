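Package: holoflex
Title: Conformational Ensemble Analysis of CaMKII Holoenzymes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative single-particle geometry analysis of
    CaMKII-alpha holoenzyme conformational ensembles. Provides a calibrated,
    seeded generator of synthetic holoenzyme particles (a rigid central hub
    with 12 or 14 flexibly tethered kinase domains), measurement of kinase
    radii of extension and clockwise neighbour separations, dataset-level
    distribution statistics with threshold-based classification of kinase
    domain pairing and compact conformations, closed-form physical models
    (random-coil linker extension, torus-volume local concentration), 2D
    particle rendering with hub/peak detection for image-level round trips,
    three-filter sensitized-emission FRET bleed-through correction, and
    variable-slope dose-response (Hill) simulation and fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    minpack.lm,
    EBImage,
    tiff
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: StructuralBiology, Visualization, Software
RoxygenNote: 7.3.3
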