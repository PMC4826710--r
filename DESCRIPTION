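Package: nemasize
Title: Nematode Perimeter, Area, Surface Area and Volume from Morphometric Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates the perimeter, projected (silhouette) area, surface
    area and volume of a nematode from standard morphometric measurements.
    Implements a piecewise conical-frustum decomposition of the body and a
    least-squares Bezier representation of the outline, alongside the
    classical cylinder, Andrassy and Tsalolikhin estimators, with
    conversions between Cobb's percentage ratios, de Man indices and
    coordinate profiles, an independent solid-of-revolution oracle for
    verification, SVG outline export and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
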