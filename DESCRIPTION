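Package: mtbuckle
Title: Buckling of Microtubules on an Elastic Kinesin Foundation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of compression-induced buckling of microtubules coupled
    to a two-dimensional elastic substrate through kinesin cross-linkers.
    Implements the beam-on-elastic-foundation relations linking flexural
    rigidity, foundation modulus, buckling wavelength and critical force; a
    kinesin-spacing-dependent softening model of the microtubule Young's
    modulus with spring-constant extraction; crest-based measurement of
    buckling wavelength, amplitude and radius of curvature from filament
    centerline traces; breakpoint ("transitional strain") and power-law
    fitting procedures; a quasi-static discrete rod-on-springs simulator that
    reproduces the Euler-to-multiwave buckling mode transition; and a
    synthetic-data generator with known ground truth for pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, signal, jsonlite, yaml, minpack.lm
Suggests: testthat (>= 3.0.0), tiff, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
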