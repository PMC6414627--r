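Package: crestcurve
Title: Sliding-Semilandmark Analysis of 3D Anterior Tibial Crest Curvature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for diachronic 3D shape analysis of the anterior tibial
    crest from dense digitized curve polylines. Provides equidistant
    arc-length resampling of curves to fixed semilandmark configurations,
    generalized Procrustes superimposition with tangent-direction sliding of
    interior semilandmarks under Procrustes-distance minimization, shape-space
    principal component analysis with broken-stick component retention,
    permutation variants of the two-sample Hotelling T-squared test, allometry
    regression diagnostics, intra-observer measurement-error reliability, and
    mean-shape difference fields with anatomical-plane projections. Includes a
    synthetic-data generator that emulates the diachronic curvature structure
    of a multi-period skeletal study so the full pipeline can be exercised and
    validated without access to restricted skeletal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
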