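Package: meioarch
Title: Geometric Analysis of Meiosis-I Chromosome Architecture in Oocytes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing the three-dimensional architecture of
    bivalent chromosomes on the meiosis-I spindle from kinetochore spot
    coordinates, kinetochore-fibre records and chromatin envelopes.
    Implements sister-kinetochore pairing, configuration classification
    under an anisotropic optical-resolution model, kinetochore-microtubule
    attachment-mode and fibre-topology classification, bivalent rotation
    and twist scoring, arm-cohesion and univalent detection with
    whole-oocyte chromosome accounting, deterministic segregation-outcome
    prediction, and age-stratified cohort statistics (exact tests, t tests,
    age-trend regression, anaphase-timing summaries). A seeded synthetic
    cohort generator emulates confocal spindle data, including localization
    noise, sub-resolution spot merging and optional rendered intensity
    volumes with a minimal volumetric spot detector.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
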