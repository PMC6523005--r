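Package: radqc
Title: Radiographic Quality-Control Analytics: Half-Value Layer, Half-Value
    Density, and Perpendicular-Ray Geometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis toolkit for radiographic and fluoroscopic
    quality control. Fits double-exponential (beam-hardening) transmission
    curves to air-kerma-rate measurements, extracts half-value layer (HVL)
    thicknesses and half-value densities (HVD, areal-density analogue) of a
    printed plastic across tube voltages, derives linear attenuation
    coefficients and their voltage trends, and reconstructs the x-ray
    perpendicular-ray location on an image receptor from projected fiducial
    marker pairs. Includes a seeded synthetic-data generator that emulates
    the bench protocol (stepped absorber thicknesses, repeated exposures,
    polyenergetic transmission with multiplicative measurement noise) and
    cone-beam projection scenes of the marker platform, with known ground
    truth for validation.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
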