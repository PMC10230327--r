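Package: clearwing
Title: Thin-Film, Effective-Medium and FDTD Optics of Clearwing Butterfly
    Wing Nanostructures, with Sessile-Drop Wettability Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the optics and wettability of transparent butterfly
    wing patches. Provides an exact transfer-matrix solver for planar
    multilayer stacks at normal incidence, effective-medium homogenization
    of subwavelength nipple arrays and microrib gratings, a from-scratch
    2D finite-difference time-domain (Yee grid) electromagnetic solver
    with periodic lateral boundaries and convolutional PML, estimation of
    pigment extinction coefficients from absorbance spectra, spectrum
    analytics (extremum detection, band statistics, spectrum comparison),
    builders for wing-membrane and scale optical models, sessile-drop
    contact-angle extraction by circular-cap fitting with group
    comparisons, and seeded synthetic-data generators emulating
    microspectrophotometry and goniometry measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    pracma,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
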