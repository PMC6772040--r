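Package: avref
Title: Average-Volume Reference Spaces for Whole-Body Image Registration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Construction of a reference space with zero average voxel-wise
    volume change for multi-subject deformable registration of whole-body
    volume images. Provides displacement-field algebra (spacing-aware
    Jacobian determinants, composition, inversion, warping), the clamped
    log-domain geometric-mean Jacobian of a cohort, synthesis of a
    displacement field with a prescribed Jacobian determinant, multi-channel
    deformable registration minimizing a sum-of-squared-differences plus
    diffusion-regularization energy, an evaluation-metric suite (signed
    symmetric volume change, average absolute volume change, inverse
    consistency error, mean squared error, mutual information, Dice overlap
    with majority-vote label fusion), seeded synthetic phantoms, and NIfTI
    input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
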