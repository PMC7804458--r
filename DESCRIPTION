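Package: tweezercal
Title: Optical-Tweezers Calibration of AFM Colloidal-Probe Cantilevers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Calibrates the spring constant of atomic force microscopy (AFM)
    colloidal-probe cantilevers by direct force measurement with optical
    tweezers. Implements trap-stiffness calibration from viscous-drag sweeps
    (Stokes drag with Faxen's wall correction), single-ray geometric-optics
    trapping forces with Fresnel coefficients, sub-pixel bead-center
    localization from bright-field images via the circumcenter construction
    and least-squares circle fits, per-power spring-constant extraction
    through Hooke's law, and constant or logarithmic-plus-plateau cantilever
    models for rectangular and V-shape levers. A seeded synthetic-data
    generator emulates drag sweeps, bead images and full calibration runs
    with known ground truth, so every stage is testable without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    optparse,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
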