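Package: bladdervol
Title: Bladder Volume Estimation from Two-View Ultrasound Segmentations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates urinary bladder volume from a pair of 2D B-mode
    ultrasound segmentation masks (transverse and sagittal view). Implements
    the traditional prolate-ellipsoid estimator (Width x Height x Length x
    0.52) and a superellipse slice-stacking 3D reconstruction in which the
    sagittal cross-section is rescaled along the transverse width according
    to a Lame-curve lateral profile and the rescaled slices are summed into
    a volume. Ships voxel phantom generators with brute-force ground-truth
    volumes, a seeded synthetic cohort simulator, and a method-agreement
    battery (percentage errors, Pearson correlation, Bland-Altman limits of
    agreement, paired t and Wilcoxon signed-rank tests, volume-group
    stratification).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    png,
    tiff,
    yaml,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
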