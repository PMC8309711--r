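# bladdervol

Bladder volume estimation from two-view B-mode ultrasound segmentations,
for urologists, sonographers and medical-imaging researchers who need
post-void residual (PVR) volumetry from conventional 2D probes rather
than dedicated 3D bladder scanners.

Conventional practice reads three calipers off the two standard views —
maximal width *W* from the transverse view, maximal height *H* and length
*L* from the sagittal view — and applies the prolate-ellipsoid formula

    V_trad = W × H × L × 0.52        (lengths in cm, volume in mL)

which systematically underestimates because pelvic confinement flattens
the bladder laterally. This package implements, alongside that
traditional estimator, a 3D reconstruction that keeps the same two
segmentation masks but models the lateral profile as a superellipse
(Lamé curve) |x/a|ⁿ + |y/b|ⁿ = 1. The two views are aligned on the
*crossover* — the transverse column of maximal vertical extent — and a
new sagittal slice is generated for every transverse column *i* in the
width span by rescaling the crossover sagittal section S_c:

    V_rec = Σᵢ S_c · (1 − |xᵢ/a|ⁿ)^(1/n) / (1 − |x_c/a|ⁿ)^(1/n) · Δx

with a = W/2, xᵢ the column-centre offset from the width midpoint, x_c
the crossover offset and Δx the column spacing. n = 2 is the ellipse;
n = 4 (the default) is the near-cuboidal profile that performs best for
adult bladders; estimates grow monotonically in n for bladder-like
inputs.

The package also provides voxel **phantoms** with brute-force
ground-truth volumes (ellipsoids and superellipse-profiled stacks, with
optional boundary perturbation), a seeded **synthetic cohort** generator,
and the standard **method-agreement battery**: MPE/MAPE, Pearson
correlation, Bland–Altman limits of agreement, paired t and Wilcoxon
signed-rank tests, and 0–200/200–400/400–600/>600 mL volume-group
stratification.

## Worked example

Make a synthetic bladder of known volume, write its two views to disk,
and estimate from the files — exactly the path a clinical mask pair
would take:

```r
library(bladdervol)

dir <- tempfile()
ph <- runPhantom(dir, shape = "model", widthMM = 100, heightMM = 80,
                 lengthMM = 110, exponent = 4, spacingMM = 1,
                 perturbAmp = 0.05, phase = 0.7)
ph$truth$true_volume_mL
#> [1] 639.475

res <- runEstimate(ph$transverse, ph$sagittal, sidecar = ph$sidecar)
res$measurements[c("width_mm", "height_mm", "length_mm", "x_c_mm")]
#> $width_mm   [1] 99
#> $height_mm  [1] 77
#> $length_mm  [1] 115
#> $x_c_mm     [1] 0

round(unlist(res$estimates), 1)
#>       est_traditional_mL est_reconstruction_n2_mL est_reconstruction_n3_mL
#>                    455.9                    538.0                    605.2
#> est_reconstruction_n4_mL est_reconstruction_n5_mL
#>                    635.2                    651.0
```

The true volume is 639.5 mL. The ellipsoid formula gives 455.9 mL
(−28.7%), while the reconstruction with the matching exponent n = 4
gives 635.2 mL (−0.7%); the estimates increase with n, bracketing the
truth between n = 4 and n = 5. A cohort-level comparison is one call:

```r
rep <- runCohortEvaluate(40, seed = 1, outCSV = "cohort.csv",
                         outReport = "report.json")
rep$report$methods$est_reconstruction_n4_mL$pooled$errors
```

A command-line front-end with `estimate`, `phantom`, `cohort` and
`evaluate` subcommands is installed at
`system.file("cli", "bladdervol.R", package = "bladdervol")`.

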