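Package: fibermech
Title: Passive Elastic Modulus Analysis for Muscle Fibers and Fiber Bundles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the passive mechanics of skinned muscle
    fibers and small fiber bundles tested by incremental stretch-relaxation.
    Converts raw force/time/sarcomere-length recordings into stress-strain
    curves and tangent elastic moduli at a fixed sarcomere strain, models
    specimen cross-sections as ellipses from orthogonal top/side diameter
    readings, predicts bundle modulus from extracellular-matrix content with
    a rule-of-mixtures composite model and a thin basement-membrane shell
    model, measures collagen-I area fractions from labeled section images
    under paired internal/external segmentations, and runs the cohort-level
    statistics (upper-IQR outlier filtering, CSA-modulus regression,
    one-sample Wilcoxon signed-rank shape tests). Includes a seeded
    synthetic-cohort generator so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    minpack.lm,
    ggplot2,
    png,
    tiff,
    yaml
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
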