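Package: achesense
Title: Colorimetric Acetylcholinesterase Biosensor Quantification and
    Framework Morphometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for digitizing smartphone images of colorimetric
    acetylcholinesterase (AChE) pesticide assays and quantifying the
    porosity of enzyme-hosting metal-organic frameworks. Provides a
    catalog of RGB/HSV color-index algorithms (including the G/(R+B)
    ratio), log-linear concentration-response calibration with k-sigma
    limit-of-detection estimation, Ellman-type inhibition-efficiency
    scoring, Michaelis-Menten kinetics fitting, and a Delaunay
    point-spacing morphometry statistic with confidence-threshold
    pruning of spurious inter-particle edges. A synthetic-data module
    generates every input with known ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deldir,
    grDevices,
    jsonlite,
    minpack.lm,
    png,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
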