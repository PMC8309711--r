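#' Accessors for bladdervol classes
#'
#' Small accessor generics so user code never touches slots directly:
#' `pixelMatrix()` returns the 0/1 matrix of a mask, `colSpacing()` /
#' `rowSpacing()` its pixel spacing in mm, `viewLabel()` its view label,
#' `volumeML()` the numeric volume of an estimate, `trueVolumeML()` the
#' ground-truth volume of a phantom, `voxelArray()` / `voxelSpacing()` /
#' `shapeParams()` the contents of a phantom.
#'
#' @param x a bladdervol object.
#' @return the corresponding slot value.
#' @name accessors
#' @aliases pixelMatrix colSpacing rowSpacing viewLabel volumeML
#'   trueVolumeML voxelArray voxelSpacing shapeParams
NULL

#' @rdname accessors
#' @export
setGeneric("pixelMatrix", function(x) standardGeneric("pixelMatrix"))
#' @rdname accessors
#' @export
setGeneric("colSpacing", function(x) standardGeneric("colSpacing"))
#' @rdname accessors
#' @export
setGeneric("rowSpacing", function(x) standardGeneric("rowSpacing"))
#' @rdname accessors
#' @export
setGeneric("viewLabel", function(x) standardGeneric("viewLabel"))
#' @rdname accessors
#' @export
setGeneric("volumeML", function(x) standardGeneric("volumeML"))
#' @rdname accessors
#' @export
setGeneric("trueVolumeML", function(x) standardGeneric("trueVolumeML"))
#' @rdname accessors
#' @export
setGeneric("voxelArray", function(x) standardGeneric("voxelArray"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("shapeParams", function(x) standardGeneric("shapeParams"))

#' @rdname accessors
setMethod("pixelMatrix", "PixelGrid2D", function(x) x@pixels)
#' @rdname accessors
setMethod("colSpacing", "PixelGrid2D", function(x) x@spacingColMM)
#' @rdname accessors
setMethod("rowSpacing", "PixelGrid2D", function(x) x@spacingRowMM)
#' @rdname accessors
setMethod("viewLabel", "PixelGrid2D", function(x) x@viewLabel)
#' @rdname accessors
setMethod("volumeML", "VolumeEstimate", function(x) x@volumeML)
#' @rdname accessors
setMethod("trueVolumeML", "Phantom3D", function(x) x@trueVolumeML)
#' @rdname accessors
setMethod("voxelArray", "Phantom3D", function(x) x@voxels)
#' @rdname accessors
setMethod("voxelSpacing", "Phantom3D", function(x) x@spacingMM)
#' @rdname accessors
setMethod("shapeParams", "Phantom3D", function(x) x@shapeParams)

#' @rdname accessors
#' @export
setGeneric("transverseView", function(x) standardGeneric("transverseView"))
#' @rdname accessors
#' @export
setGeneric("sagittalView", function(x) standardGeneric("sagittalView"))
#' @rdname accessors
#' @export
setGeneric("crossoverInfo", function(x) standardGeneric("crossoverInfo"))
#' @rdname accessors
setMethod("transverseView", "ViewPair", function(x) x@transverse)
#' @rdname accessors
setMethod("sagittalView", "ViewPair", function(x) x@sagittal)
#' @rdname accessors
setMethod("crossoverInfo", "ViewPair", function(x) x@crossover)

setMethod("show", "PixelGrid2D", function(object) {
  d <- dim(object@pixels)
  cat(sprintf(
    "PixelGrid2D [%s view]: %d x %d px, spacing %.3g x %.3g mm, %d foreground px\n",
    object@viewLabel, d[1L], d[2L], object@spacingRowMM, object@spacingColMM,
    sum(object@pixels)))
})

setMethod("show", "CrossoverInfo", function(object) {
  cat(sprintf("CrossoverInfo: column %d, x_c = %.3g mm\n",
              object@columnIndex, object@xcMM))
})

setMethod("show", "ViewPair", function(object) {
  cat("ViewPair\n  ")
  show(object@transverse)
  cat("  ")
  show(object@sagittal)
  cat("  ")
  show(object@crossover)
})

setMethod("show", "SuperellipseProfile", function(object) {
  cat(sprintf("SuperellipseProfile: a = %.3g mm, n = %.3g\n",
              object@halfWidthAMM, object@exponent))
})

setMethod("show", "VolumeEstimate", function(object) {
  if (object@method == "traditional")
    cat(sprintf("VolumeEstimate [traditional]: %.2f mL\n", object@volumeML))
  else
    cat(sprintf("VolumeEstimate [reconstruction, n = %.3g]: %.2f mL\n",
                object@exponent, object@volumeML))
})

setMethod("show", "SliceStack3D", function(object) {
  d <- dim(object@slices[[1L]])
  cat(sprintf(
    "SliceStack3D: %d slices of %d x %d px, slice spacing %.3g mm, volume %.2f mL\n",
    length(object@slices), d[1L], d[2L], object@sliceSpacingMM,
    stackVolume(object)))
})

setMethod("show", "Phantom3D", function(object) {
  d <- dim(object@voxels)
  cat(sprintf(
    "Phantom3D [%s]: %d x %d x %d voxels, spacing (%.3g, %.3g, %.3g) mm, true volume %.2f mL\n",
    if (is.null(object@shapeParams$shape)) "custom" else object@shapeParams$shape,
    d[1L], d[2L], d[3L],
    object@spacingMM[1L], object@spacingMM[2L], object@spacingMM[3L],
    object@trueVolumeML))
})
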