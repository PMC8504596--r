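Package: imbect
Title: Planning and Verification for Intensity-Modulated Bolus Electron
    Conformal Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning and verifying intensity-modulated bolus
    electron conformal therapy (IM-BECT). Provides an analytic electron beam
    model, synthetic phantom and aperture fixtures, a Fermi-Eyges pencil-beam
    dose engine with island-block (tungsten pin) fluence modulation, the bolus
    design operator set (create, isodose shift, smooth, specified shift,
    truncate, height extension), derivation of intensity-reduction-factor maps
    from ray-line maximum dose, segmentation of intensity maps into hexagonal
    island-block patterns with iterative refinement, and planar quality
    assurance by dose-difference and distance-to-agreement analysis together
    with DVH plan metrics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
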