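Package: oxyCT
Title: Simulated Phase-Contrast Cone-Beam CT Monitoring of Thrombus Growth
    in Membrane Oxygenators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An in-silico pipeline for visualizing and quantifying thrombus
    growth inside hollow-fiber membrane oxygenators with cone-beam computed
    tomography. Provides digital phantoms of an annular coiled-fiber
    oxygenator with red (erythrocyte-rich) and white (platelet/fibrin-rich)
    thrombi, Beer-Lambert cone-beam forward projection with Poisson noise
    and detector gain structure, flat-field correction and ring-artifact
    suppression, FDK filtered back-projection with a linear ramp filter,
    serial-scan alignment and baseline subtraction, size- and
    contrast-filtered red/white thrombus segmentation with volume
    quantification, and analytics for extracorporeal-circuit monitoring
    data (pressure drop, platelet and red-cell counts, ACT, aPTT) including
    sample-acceptance filters, loop geometry ratios and
    experiment-termination detection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
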