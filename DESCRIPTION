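Package: vesiconc
Title: Vesicle Weight Concentration from Static and Dynamic Light Scattering
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Determines the weight concentration of extruded unilamellar
    vesicle (liposome) dispersions from relative static light-scattering
    intensities of the two sequential extrusion samples, solving the
    mass-closure system in closed form with first-order error propagation.
    Includes dynamic light scattering characterization by cumulants analysis
    and by a regularized inverse Laplace transform of the intensity
    autocorrelation function, a thin-shell vesicle mass model with its
    detection-limit scaling, a Rayleigh-ratio standard shortcut, elastic-peak
    integration of spectrofluorimeter spectra as an intensity proxy, weighted
    calibration and inverse prediction for the Stewart colorimetric
    phospholipid assay, and a forward simulator that generates every input
    the pipeline consumes with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    pracma,
    yaml
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
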