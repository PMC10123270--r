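Package: axelong
Title: Axial-Length Increment Modelling from Corneal Geometry and Refraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes measured ocular axial length into an emmetropic
    component determined by corneal curvature and a myopia-attributable axial
    increment, using the Morgan reciprocal-length formula. Provides the
    closed-form model (Morgan axial-length estimate, emmetropic axial length,
    axial increment and their algebraic inverses), a calibrated synthetic
    ocular-biometry cohort generator whose moments and structural regression
    coefficients match a target clinical population, and a statistical
    pipeline covering Pearson correlation, Bland-Altman agreement, simple and
    covariate-adjusted linear regression of biometric outcomes on corneal
    stiffness (stress-strain index), long-eye subgroup models, group
    summaries, regression diagnostics, and record-level exclusion filtering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    lmtest,
    nortest
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
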