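Package: oofdose
Title: Out-of-Field Dose Comparison for Pediatric Photon Radiotherapy
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline for comparing out-of-field (peripheral) organ
    doses between 3D conformal (3DCRT) and intensity-modulated (IMRT)
    radiotherapy of a pediatric brain target. Provides parametric voxel
    phantoms with organs placed at clinical centre-to-centre distances, a
    treatment-plan and dynamic multileaf-collimator (MLC) log-file data model
    with control-point subsampling, a simplified Monte Carlo photon transport
    engine (Woodcock delta-tracking, Klein-Nishina Compton scattering,
    photoelectric absorption, pair production, track-length kerma estimation,
    Russian roulette and splitting), a thermoluminescent-dosimeter (TLD)
    air-kerma reduction chain with a quadrature uncertainty budget, comparison
    statistics between dose sources and techniques, and synthetic-data
    generators for every input so the whole chain runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
Config/testthat/edition: 3
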