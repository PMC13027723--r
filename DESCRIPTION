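Package: rbcflicker
Title: Erythrocyte Morphometry and Membrane Flickering Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational-microscopy toolkit for mechanical phenotyping of
    red blood cells. Segments bright-field cell fields into accepted
    single-cell contours with shape-based quality filters, computes
    morphomechanical descriptors (area, perimeter, circularity, form factor,
    elongation, contour fluctuation amplitude), estimates an effective
    lateral membrane tension from ensemble-averaged contour Fourier-mode
    spectra, and extracts per-cell viscoelastic descriptors (effective
    rigidity, Einstein diffusivity, friction, relaxation frequency,
    volatility) from high-speed contour fluctuation time series under an
    overdamped Langevin description. Includes a Harboe-based hemolysis
    readout with blank-propagated limits of detection, nonparametric group
    reporting with trend banding, and a synthetic-data generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
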