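Package: stedao
Title: Genetic-Algorithm Wavefront Correction for STED Microscopy on a
    Simulated Optical Bench
Version: 0.1.0
Authors@R: person("stedao", "maintainers", email = "stedao@example.org",
    role = c("aut", "cre"))
Description: Sensorless adaptive optics for stimulated emission depletion
    (STED) microscopy. Models the pupil-plane phase masks carried by a
    spatial light modulator (blazed grating, vortex, Zernike and segmented
    correction phases), computes scalar focal-plane point spread functions,
    and optimizes the correction phase with an elitist genetic algorithm
    driven by a simulated guide-star scattering signal. Includes a
    saturated-depletion effective-PSF model, synthetic aberration screens
    and emitter phantoms, image-quality metrics (Gaussian-fit FWHM, donut
    null depth, ring uniformity, mean intensity), mask/image I/O (BMP, PGM,
    float TIFF, CSV) and a scenario runner with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
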