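Package: hyperstress
Title: Hyperspectral Plant-Stress Phenotyping by Equality-Constrained MCR-ALS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of visible/near-infrared hyperspectral
    reflectance images of Arabidopsis rosettes under chemical stress.
    Provides ENVI cube input/output with white/dark reflectance calibration,
    band-ratio plant-pixel segmentation with leaf- and root-area
    quantification, multivariate curve resolution by alternating least
    squares (MCR-ALS) with non-negativity and equality constraints, a
    constant-offset baseline component, data-driven model-order selection
    (scree elbow, residual PCA, null-component detection), Games-Howell
    heteroscedastic post-hoc comparisons of per-plant component intensities,
    and a synthetic-scene generator with known ground truth for validating
    every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
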