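Package: ngfreg
Title: Masked Normalized-Gradient-Fields Registration for Longitudinal
    Brain MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Deformable registration of pre- and post-operative brain MRI
    volumes by variational minimization of a masked normalized-gradient-fields
    image distance with curvature regularization and optional volume-change
    control, optimized with multi-level quasi-Newton (l-BFGS) descent.
    Pathological tissues without a counterpart across time points (e.g. a
    resection cavity) are excluded from the distance via a binary mask.
    Provides NIfTI input/output for volumes, masks and displacement fields,
    landmark-based target registration error evaluation with paired Wilcoxon
    signed-rank comparisons, a synthetic longitudinal phantom generator with
    ground-truth deformations, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    RNifti,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
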