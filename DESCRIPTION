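Package: circumpen
Title: Circumnutating Cone-Penetrometer Mechanics and Soil-Structure Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for root-analogue cone-penetrometer
    experiments in which soil samples are subjected to orbital motion to
    mimic root circumnutation. Converts projected probe-deflection angles
    into horizontal cone deflection, circumnutation amplitude and axial
    force corrections; decomposes axial penetration force into cavity
    expansion and interfacial friction components via cavity expansion
    theory, including asymmetry and circumnutation-intensity indices and
    friction-coefficient rescaling; quantifies soil structure around the
    cone imprint from binary X-ray computed tomography volumes (imprint
    isolation by distance-transform watershed, radial visible-porosity and
    compactness profiles, bulk-density estimates); and provides a seeded
    synthetic-data generator (force traces, deflection series, CT phantoms)
    together with the treatment-level statistics (ANCOVA, LSD letters,
    least-squares regressions).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    car,
    jsonlite,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
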