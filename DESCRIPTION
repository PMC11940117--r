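Package: tesfield
Title: Transcranial Electrical Stimulation Field Modelling in Layered Head Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the intracranial electric field induced by transcranial
    electrical stimulation (tES) in multilayer spherical head phantoms. Provides
    a synthetic aging-cohort generator with age-dependent layer anatomy, a P1
    tetrahedral finite-element solver for the quasi-static conduction equation,
    an analytic multilayer-sphere Legendre-series forward solution used as an
    independent oracle, standard field outcome metrics (percentile peak,
    focality, region-of-interest amplitudes), anatomical predictors (relative
    tissue volumes, under-electrode layer thicknesses), and the statistical
    layer (decade group summaries, independent t-tests, standardized
    backward-elimination stepwise regression, trend-shape classification)
    needed to study how cortical field amplitude changes over the adult
    lifespan.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
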