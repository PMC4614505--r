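Package: fibrilmech
Title: Single Collagen Fibril Mechanics and Hydration from AFM Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for atomic force microscopy (AFM) studies of
    individual collagen fibrils. Converts cantilever-based nanoindentation
    force-displacement curves into indentation moduli via Sneddon/Oliver-Pharr
    contact mechanics (thermal spring-constant calibration, contact-point
    detection, contact stiffness, projected area function, reduced and sample
    modulus); extracts fibril geometry from height topographies (axis tracing,
    cross-section height, D-band periodicity, hydration swelling, water
    fraction and normalized density); provides the unit-cell, mass-density and
    tangent-modulus arithmetic used to compare wild-type and homotrimeric
    (oim) collagen microfibrils; and compares fibril cohorts with a Gaussian
    linear model on log-moduli with least-square means and Tukey-adjusted
    pairwise contrasts. A synthetic-data module generates force curves,
    D-banded fibril topographies and cohorts with known ground truth so the
    whole chain is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    tiff,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
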