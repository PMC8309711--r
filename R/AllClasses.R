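#' @import methods
#' @importFrom stats integrate sd cor t.test wilcox.test pnorm runif
NULL

#' Single-view binary segmentation mask with physical pixel spacing
#'
#' A `PixelGrid2D` holds one binary ultrasound segmentation (rows x columns,
#' row 1 at the top of the image, column 1 at the left) together with the
#' physical size of a pixel along each axis, in millimetres. Nonzero pixels
#' are bladder ("foreground"). The view label records which standard
#' ultrasound plane the mask depicts: the transverse view supplies the
#' maximal bladder width, the sagittal view the maximal height and length.
#'
#' @slot pixels integer matrix of 0/1 values; 1 = bladder.
#' @slot spacingColMM horizontal size of one pixel, mm (> 0).
#' @slot spacingRowMM vertical size of one pixel, mm (> 0).
#' @slot viewLabel one of `"transverse"`, `"sagittal"`, `"unspecified"`.
#'
#' @seealso [PixelGrid2D()] for the user-facing constructor, [loadMask()]
#'   to read a mask from a PNG/TIFF file.
#' @exportClass PixelGrid2D
setClass("PixelGrid2D",
  representation(
    pixels       = "matrix",
    spacingColMM = "numeric",
    spacingRowMM = "numeric",
    viewLabel    = "character"
  )
)

setValidity("PixelGrid2D", function(object) {
  msg <- character()
  p <- object@pixels
  if (length(dim(p)) != 2L || nrow(p) < 1L || ncol(p) < 1L)
    msg <- c(msg, "'pixels' must be a non-degenerate matrix")
  if (!all(p %in% c(0L, 1L)))
    msg <- c(msg, "'pixels' must be binary (0/1)")
  for (s in c("spacingColMM", "spacingRowMM")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("'%s' must be a single positive finite number", s))
  }
  if (length(object@viewLabel) != 1L ||
      !object@viewLabel %in% c("transverse", "sagittal", "unspecified"))
    msg <- c(msg, "'viewLabel' must be transverse, sagittal or unspecified")
  if (length(msg)) msg else TRUE
})

#' Crossover column of a transverse mask
#'
#' The crossover is the transverse-view column of maximal vertical bladder
#' extent: the line along which the sagittal imaging plane intersects the
#' transverse plane, and hence the line on which the two views are aligned
#' before slice-stacking. `xcMM` is the signed offset of that column's
#' centre from the midpoint of the mask's width span, in mm (0 when the
#' tallest column sits exactly at the middle of the width).
#'
#' @slot columnIndex 1-based column index into the transverse mask.
#' @slot xcMM signed offset of the column centre from the width midpoint (mm).
#' @seealso [crossoverColumn()]
#' @exportClass CrossoverInfo
setClass("CrossoverInfo",
  representation(columnIndex = "integer", xcMM = "numeric")
)

#' Aligned transverse + sagittal mask pair for one bladder
#'
#' The two standard views of one bladder, plus the crossover information of
#' the transverse mask used to align them. This is the input unit of both
#' volume estimators.
#'
#' @slot transverse,sagittal [PixelGrid2D-class] masks; both nonempty.
#' @slot crossover [CrossoverInfo-class] computed on the transverse mask.
#' @seealso [ViewPair()], [reconstructVolume()], [traditionalVolume()]
#' @exportClass ViewPair
setClass("ViewPair",
  representation(
    transverse = "PixelGrid2D",
    sagittal   = "PixelGrid2D",
    crossover  = "CrossoverInfo"
  )
)

setValidity("ViewPair", function(object) {
  msg <- character()
  if (sum(object@transverse@pixels) == 0L)
    msg <- c(msg, "transverse mask is empty")
  if (sum(object@sagittal@pixels) == 0L)
    msg <- c(msg, "sagittal mask is empty")
  if (sum(object@transverse@pixels) > 0L) {
    cols <- range(which(colSums(object@transverse@pixels) > 0L))
    ci <- object@crossover@columnIndex
    if (ci < cols[1L] || ci > cols[2L])
      msg <- c(msg, "crossover column lies outside the transverse width span")
  }
  if (length(msg)) msg else TRUE
})

#' Superellipse lateral profile of the bladder
#'
#' The reconstruction assumes the bladder's lateral (left-right) extent
#' follows a superellipse (Lame curve) |x/a|^n + |y/b|^n = 1, where `a` is
#' half the maximal transverse width and `n` controls squareness: n = 2 is
#' an ellipse, larger n approaches a rectangle, emulating the flattening of
#' the bladder against the pelvic wall. Only the normalised profile factor
#' f(x) = y/b = (1 - |x/a|^n)^(1/n) is ever used, so the vertical semi-axis
#' b never appears explicitly.
#'
#' @slot halfWidthAMM half-width a in mm (> 0).
#' @slot exponent superellipse exponent n (> 0, need not be an integer).
#' @seealso [profileFactor()], [profileIntegral()]
#' @exportClass SuperellipseProfile
setClass("SuperellipseProfile",
  representation(halfWidthAMM = "numeric", exponent = "numeric")
)

setValidity("SuperellipseProfile", function(object) {
  msg <- character()
  if (length(object@halfWidthAMM) != 1L || !is.finite(object@halfWidthAMM) ||
      object@halfWidthAMM <= 0)
    msg <- c(msg, "half-width a must be a single positive number")
  if (length(object@exponent) != 1L || !is.finite(object@exponent) ||
      object@exponent <= 0)
    msg <- c(msg, "exponent n must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' A bladder volume estimate
#'
#' @slot method `"traditional"` (prolate-ellipsoid formula) or
#'   `"reconstruction"` (superellipse slice stacking).
#' @slot exponent superellipse exponent used; `NA` for the traditional method.
#' @slot volumeML estimated volume in mL (>= 0).
#' @seealso [traditionalVolume()], [reconstructVolume()]
#' @exportClass VolumeEstimate
setClass("VolumeEstimate",
  representation(method = "character", exponent = "numeric",
                 volumeML = "numeric")
)

setValidity("VolumeEstimate", function(object) {
  msg <- character()
  if (!object@method %in% c("traditional", "reconstruction"))
    msg <- c(msg, "method must be 'traditional' or 'reconstruction'")
  if (length(object@volumeML) != 1L || !is.finite(object@volumeML) ||
      object@volumeML < 0)
    msg <- c(msg, "volumeML must be a single nonnegative number")
  if (length(msg)) msg else TRUE
})

#' Stack of rescaled sagittal slices forming a reconstructed 3D bladder
#'
#' One slice per transverse column in the bladder's width span. Slice i is
#' the original sagittal mask rescaled vertically (about its foreground
#' centroid) by the superellipse factor of that column; the slice at the
#' crossover column is the original sagittal mask unchanged.
#'
#' @slot slices list of binary matrices (rows = sagittal rows,
#'   cols = sagittal columns), in width-span order.
#' @slot sliceSpacingMM distance between consecutive slices = transverse
#'   column spacing (mm).
#' @slot spacingColMM,spacingRowMM in-slice pixel spacing, inherited from
#'   the sagittal mask (mm).
#' @slot crossoverIndex index into `slices` of the crossover slice.
#' @seealso [buildSliceStack()], [stackVolume()]
#' @exportClass SliceStack3D
setClass("SliceStack3D",
  representation(
    slices         = "list",
    sliceSpacingMM = "numeric",
    spacingColMM   = "numeric",
    spacingRowMM   = "numeric",
    crossoverIndex = "integer"
  )
)

#' Voxel phantom with brute-force ground-truth volume
#'
#' A synthetic 3D bladder of exactly known volume, used to validate the
#' estimators without clinical images. The ground truth is always the voxel
#' count times the voxel volume (never an analytic formula), so perturbed
#' and irregular shapes remain testable. Axis convention: array dimension 1
#' is the vertical (height, y) axis, dimension 2 the transverse horizontal
#' (width, x) axis, dimension 3 the sagittal horizontal (length, z) axis.
#'
#' @slot voxels 3D 0/1 integer array `[ny, nx, nz]`.
#' @slot spacingMM numeric length-3 voxel size in mm, in axis order
#'   (height, width, length).
#' @slot trueVolumeML voxel count x voxel volume / 1000 (mL).
#' @slot shapeParams named list recording the generating parameters.
#' @seealso [makeEllipsoidPhantom()], [makeModelPhantom()], [projectViews()]
#' @exportClass Phantom3D
setClass("Phantom3D",
  representation(
    voxels       = "array",
    spacingMM    = "numeric",
    trueVolumeML = "numeric",
    shapeParams  = "list"
  )
)

setValidity("Phantom3D", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "'voxels' must be a 3D array")
  if (!all(object@voxels %in% c(0L, 1L)))
    msg <- c(msg, "'voxels' must be binary (0/1)")
  if (length(object@spacingMM) != 3L || any(!is.finite(object@spacingMM)) ||
      any(object@spacingMM <= 0))
    msg <- c(msg, "'spacingMM' must be 3 positive numbers")
  v <- sum(object@voxels) * prod(object@spacingMM) / 1000
  if (!isTRUE(all.equal(v, object@trueVolumeML)))
    msg <- c(msg, "trueVolumeML does not match the voxel count")
  if (object@trueVolumeML <= 0)
    msg <- c(msg, "phantom is empty")
  if (length(msg)) msg else TRUE
})
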