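#' Construct a PixelGrid2D from a matrix
#'
#' Any nonzero value in `pixels` is treated as bladder foreground; this is
#' deliberately permissive because segmentation masks come from
#' heterogeneous annotation tools (0/1, 0/255, 16-bit, float).
#'
#' @param pixels numeric/integer/logical matrix; nonzero = foreground.
#' @param spacingColMM horizontal pixel size in mm (> 0).
#' @param spacingRowMM vertical pixel size in mm (> 0); defaults to
#'   `spacingColMM` (square pixels).
#' @param viewLabel `"transverse"`, `"sagittal"` or `"unspecified"`.
#' @return a [PixelGrid2D-class] object.
#' @examples
#' m <- matrix(0, 8, 8); m[3:6, 2:7] <- 1
#' PixelGrid2D(m, spacingColMM = 0.5, viewLabel = "transverse")
#' @export
PixelGrid2D <- function(pixels, spacingColMM, spacingRowMM = spacingColMM,
                        viewLabel = "unspecified") {
  if (!is.matrix(pixels))
    stop("'pixels' must be a matrix")
  bin <- matrix(as.integer(pixels != 0), nrow = nrow(pixels))
  new("PixelGrid2D", pixels = bin,
      spacingColMM = as.numeric(spacingColMM),
      spacingRowMM = as.numeric(spacingRowMM),
      viewLabel = viewLabel)
}

#' Load a binary segmentation mask from a PNG or TIFF file
#'
#' Reads a single-channel, greyscale+alpha or RGB(A) raster and binarizes
#' it: any pixel with a nonzero value in any colour channel becomes
#' foreground, so a white-on-black RGB mask and its greyscale version yield
#' the same foreground set. The alpha channel, if present, is ignored.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @param spacingColMM,spacingRowMM physical pixel size in mm (> 0).
#' @param viewLabel `"transverse"`, `"sagittal"` or `"unspecified"`.
#' @return a [PixelGrid2D-class] object.
#' @seealso [preprocessMask()] to clean a freshly loaded mask.
#' @export
loadMask <- function(path, spacingColMM, spacingRowMM = spacingColMM,
                     viewLabel = "unspecified") {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("mask file not found: ", path)
  if (spacingColMM <= 0 || spacingRowMM <= 0)
    stop("pixel spacings must be strictly positive")
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported mask format '", ext, "' (use PNG or TIFF)"))
  if (length(dim(img)) == 3L) {
    nch <- dim(img)[3L]
    # drop alpha (channel 2 of GA, channel 4 of RGBA) before binarizing
    keep <- if (nch %in% c(2L, 4L)) seq_len(nch - 1L) else seq_len(nch)
    img <- apply(img[, , keep, drop = FALSE], c(1L, 2L), max)
  }
  if (length(img) == 0L)
    stop("zero-sized image: ", path)
  PixelGrid2D(img, spacingColMM, spacingRowMM, viewLabel)
}

#' Write a mask to a PNG file
#'
#' Foreground is written as white (1.0), background as black.
#'
#' @param mask a [PixelGrid2D-class].
#' @param path output `.png` path.
#' @return `path`, invisibly.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "PixelGrid2D"))
  png::writePNG(mask@pixels * 1.0, target = path)
  invisible(path)
}

#' Clean a segmentation mask for volumetry
#'
#' Restricts the mask to its largest 4-connected foreground component and
#' fills interior holes, guarding the downstream width/crossover
#' measurements against speckle islands and dropout holes. 4-connectivity
#' is used so that diagonal speckle bridges do not merge separate islands.
#' Idempotent: a clean mask passes through unchanged.
#'
#' @param mask a [PixelGrid2D-class] with at least one foreground pixel.
#' @return a [PixelGrid2D-class] with the same spacing and label.
#' @export
preprocessMask <- function(mask) {
  stopifnot(is(mask, "PixelGrid2D"))
  p <- mask@pixels
  if (sum(p) == 0L)
    stop("cannot preprocess an empty mask")
  lab <- EBImage::bwlabel(p)            # 4-connected labelling
  counts <- tabulate(lab[lab > 0])
  keep <- which.max(counts)
  comp <- matrix(as.integer(lab == keep), nrow = nrow(p))
  filled <- EBImage::fillHull(comp)
  PixelGrid2D(as.matrix(filled), mask@spacingColMM, mask@spacingRowMM,
              mask@viewLabel)
}

#' Measure the horizontal and vertical extent of a mask
#'
#' Extents are inclusive pixel counts times spacing: a single foreground
#' pixel has extent equal to one pixel spacing, matching how on-screen
#' calipers include the pixel footprint.
#'
#' @param mask a nonempty [PixelGrid2D-class].
#' @return named numeric vector `c(horizontal_mm, vertical_mm)`.
#' @examples
#' m <- matrix(0, 4, 6); m[2:4, 2:6] <- 1
#' measureExtents(PixelGrid2D(m, 0.5))  # 2.5 mm x 1.5 mm
#' @export
measureExtents <- function(mask) {
  stopifnot(is(mask, "PixelGrid2D"))
  p <- mask@pixels
  if (sum(p) == 0L)
    stop("cannot measure an empty mask")
  cols <- range(which(colSums(p) > 0L))
  rows <- range(which(rowSums(p) > 0L))
  c(horizontal_mm = (cols[2L] - cols[1L] + 1L) * mask@spacingColMM,
    vertical_mm   = (rows[2L] - rows[1L] + 1L) * mask@spacingRowMM)
}

#' Locate the crossover column of a transverse mask
#'
#' The crossover is the column of maximal foreground vertical extent -- the
#' line where the sagittal plane intersects the transverse plane and the
#' two views are aligned. Ties are broken by the column closest to the
#' foreground centroid column, then by the smaller index, so symmetric
#' masks deterministically yield the central column with `xcMM = 0`.
#'
#' @param mask a nonempty [PixelGrid2D-class] (normally the transverse view).
#' @return a [CrossoverInfo-class]: the column index and its signed offset
#'   `x_c` from the width midpoint in mm.
#' @export
crossoverColumn <- function(mask) {
  stopifnot(is(mask, "PixelGrid2D"))
  p <- mask@pixels
  if (sum(p) == 0L)
    stop("cannot locate a crossover in an empty mask")
  csum <- colSums(p)
  occ <- which(csum > 0L)
  # per-column vertical extent, inclusive pixel count
  ext <- vapply(occ, function(j) {
    r <- range(which(p[, j] > 0L))
    r[2L] - r[1L] + 1L
  }, numeric(1L))
  best <- occ[ext == max(ext)]
  if (length(best) > 1L) {
    centroid <- sum(seq_len(ncol(p)) * csum) / sum(csum)
    d <- abs(best - centroid)
    best <- best[d == min(d)]
    best <- min(best)
  }
  span <- range(occ)
  xc <- (best - (span[1L] + span[2L]) / 2) * mask@spacingColMM
  new("CrossoverInfo", columnIndex = as.integer(best), xcMM = xc)
}

#' Pair the two views of one bladder
#'
#' Optionally preprocesses both masks (largest component + hole fill),
#' then computes the crossover column of the transverse mask.
#'
#' @param transverse transverse-view [PixelGrid2D-class].
#' @param sagittal sagittal-view [PixelGrid2D-class].
#' @param preprocess clean both masks first? Default `TRUE`.
#' @return a [ViewPair-class].
#' @export
ViewPair <- function(transverse, sagittal, preprocess = TRUE) {
  stopifnot(is(transverse, "PixelGrid2D"), is(sagittal, "PixelGrid2D"))
  if (preprocess) {
    transverse <- preprocessMask(transverse)
    sagittal <- preprocessMask(sagittal)
  }
  new("ViewPair", transverse = transverse, sagittal = sagittal,
      crossover = crossoverColumn(transverse))
}

#' Tri-axis caliper measurement of a view pair
#'
#' The maximal width is measured on the transverse view; the maximal
#' height and length on the sagittal view (length horizontal, height
#' vertical). These three diameters feed the traditional prolate-ellipsoid
#' volume formula.
#'
#' @param pair a [ViewPair-class].
#' @return named list with `width_mm`, `height_mm`, `length_mm`.
#' @seealso [traditionalVolume()]
#' @export
measureTriAxis <- function(pair) {
  stopifnot(is(pair, "ViewPair"))
  te <- measureExtents(pair@transverse)
  se <- measureExtents(pair@sagittal)
  list(width_mm  = unname(te["horizontal_mm"]),
       height_mm = unname(se["vertical_mm"]),
       length_mm = unname(se["horizontal_mm"]))
}

#' Read a per-view pixel-spacing sidecar file
#'
#' The sidecar is YAML (or JSON, which YAML subsumes) of the form
#' `transverse: {col_mm: 0.4, row_mm: 0.4}` / `sagittal: {col_mm: ...}`.
#'
#' @param path path to the YAML sidecar.
#' @return nested list with `$transverse$col_mm` etc.
#' @export
readSpacingSidecar <- function(path) {
  if (!file.exists(path))
    stop("spacing sidecar not found: ", path)
  sc <- yaml::read_yaml(path)
  for (v in c("transverse", "sagittal")) {
    if (is.null(sc[[v]]) || is.null(sc[[v]]$col_mm) || is.null(sc[[v]]$row_mm))
      stop("sidecar must define ", v, ": {col_mm, row_mm}")
    if (sc[[v]]$col_mm <= 0 || sc[[v]]$row_mm <= 0)
      stop("sidecar spacings must be positive")
  }
  sc
}
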