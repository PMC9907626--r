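Package: hsicolor
Title: Hyperspectral Skin Color Evaluation and Study Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for full-face hyperspectral skin color evaluation:
    calibration of raw band-sequential CCD frames (dark, flat-field and 99%
    white-standard correction) into percentage-reflectance datacubes,
    conversion of reflectance spectra and cubes to CIE XYZ and L*a*b* under
    D65 illumination with the CIE 1964 10-degree observer, landmark-anchored
    region-of-interest color statistics, first-order propagation of spectral
    noise to colorimetric uncertainties, and repeatability/reproducibility
    study analysis (one-way ANOVA with Tukey HSD product grouping, ranking
    strings, correlation and percent-nonlinearity metrics). A synthetic-data
    generator emulates skin-like reflectance spectra, product-induced color
    shifts, facial landmark layouts and complete evaluation studies so the
    whole pipeline is testable without instrument hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    withr
Config/testthat/edition: 3
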