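#' Axis-aligned ellipsoid voxel phantom
#'
#' Voxelises the ellipsoid with diameters `widthMM` (x), `heightMM` (y),
#' `lengthMM` (z) centred on the grid: a voxel is foreground iff its
#' centre lies inside the ellipsoid. The ground-truth volume is the voxel
#' count times the voxel volume; it converges to `pi/6 * W * H * L` as the
#' spacing shrinks (first order in spacing).
#'
#' @param widthMM,heightMM,lengthMM full diameters in mm (> 0).
#' @param spacingMM voxel size in mm: a scalar (isotropic) or length-3
#'   vector in axis order (height, width, length).
#' @return a [Phantom3D-class].
#' @examples
#' ph <- makeEllipsoidPhantom(40, 30, 35, spacingMM = 1)
#' trueVolumeML(ph)  # ~ pi/6 * 4 * 3 * 3.5 = 22 mL
#' @export
makeEllipsoidPhantom <- function(widthMM, heightMM, lengthMM, spacingMM = 1) {
  axes <- c(widthMM, heightMM, lengthMM)
  if (any(!is.finite(axes)) || any(axes <= 0))
    stop("all diameters must be strictly positive")
  sp <- expandSpacing(spacingMM)
  # odd dimension counts centre the ellipsoid on a voxel centre, making the
  # centre-sampling symmetric and the measured extents unbiased in the
  # sub-voxel placement of the surface
  oddDim <- function(d, s) 2L * as.integer(ceiling(d / (2 * s))) + 3L
  ny <- oddDim(heightMM, sp[1L])
  nx <- oddDim(widthMM, sp[2L])
  nz <- oddDim(lengthMM, sp[3L])
  u2 <- function(n, s, d) (((seq_len(n) - 0.5) * s - n * s / 2) / (d / 2))^2
  y2 <- u2(ny, sp[1L], heightMM)
  x2 <- u2(nx, sp[2L], widthMM)
  z2 <- u2(nz, sp[3L], lengthMM)
  inside <- outer(outer(y2, x2, "+"), z2, "+") <= 1
  vox <- array(as.integer(inside), dim = c(ny, nx, nz))
  newPhantom(vox, sp, list(shape = "ellipsoid", width_mm = widthMM,
                           height_mm = heightMM, length_mm = lengthMM,
                           spacing_mm = sp))
}

expandSpacing <- function(spacingMM) {
  if (any(!is.finite(spacingMM)) || any(spacingMM <= 0))
    stop("voxel spacing must be strictly positive")
  if (length(spacingMM) == 1L) rep(as.numeric(spacingMM), 3L)
  else if (length(spacingMM) == 3L) as.numeric(spacingMM)
  else stop("spacingMM must have length 1 or 3")
}

newPhantom <- function(vox, sp, params) {
  if (sum(vox) == 0L)
    stop("phantom is empty at this spacing")
  new("Phantom3D", voxels = vox, spacingMM = sp,
      trueVolumeML = sum(vox) * prod(sp) / 1000, shapeParams = params)
}

#' Phantom that satisfies the slice-stacking model exactly
#'
#' Stacks vertically-rescaled copies of a base sagittal mask along the
#' width (x) axis with superellipse factors f(x_i) (crossover at the
#' centre, f(0) = 1), producing a 3D shape for which the reconstruction's
#' own generative assumption holds. The central slice equals the base
#' mask; slices beyond |x| = a are empty. Used for parameter-recovery
#' tests: reconstructing the projected views with the matching exponent
#' must recover the voxel ground truth as the spacing shrinks.
#'
#' @param baseSagittal nonempty sagittal [PixelGrid2D-class]; its pixel
#'   spacings become the in-slice voxel spacings.
#' @param halfWidthAMM half-width a of the lateral profile, mm (> 0).
#' @param exponentN superellipse exponent (> 0).
#' @param spacingMM slice spacing along the width axis, mm (> 0, scalar).
#' @return a [Phantom3D-class]; an odd number of slices, centred at x = 0.
#' @export
makeModelPhantom <- function(baseSagittal, halfWidthAMM, exponentN,
                             spacingMM = 1) {
  stopifnot(is(baseSagittal, "PixelGrid2D"))
  if (sum(baseSagittal@pixels) == 0L)
    stop("base sagittal mask is empty")
  if (halfWidthAMM <= 0 || exponentN <= 0 || spacingMM <= 0)
    stop("half-width, exponent and spacing must be strictly positive")
  a <- halfWidthAMM
  s <- as.numeric(spacingMM)
  nx <- 2L * as.integer(ceiling(a / s)) - 1L
  x <- (seq_len(nx) - (nx + 1L) / 2) * s
  f <- ifelse(abs(x) >= a, 0, superellipseFactor(pmin(abs(x), a), a, exponentN))
  base <- baseSagittal@pixels
  rows <- which(base > 0L, arr.ind = TRUE)[, 1L]
  rc <- mean(rows - 0.5)
  d <- dim(base)
  vox <- array(0L, dim = c(d[1L], nx, d[2L]))
  for (i in seq_len(nx)) {
    if (f[i] == 1) vox[, i, ] <- base
    else if (f[i] > 0) vox[, i, ] <- rescaleVertical(base, f[i], rc)
  }
  newPhantom(vox,
             c(baseSagittal@spacingRowMM, s, baseSagittal@spacingColMM),
             list(shape = "model", half_width_a_mm = a,
                  exponent_n = exponentN, spacing_mm = s))
}

#' Elliptical (optionally perturbed) sagittal base mask
#'
#' Rasterises an ellipse with horizontal diameter `lengthMM` and vertical
#' diameter `heightMM`, optionally modulated by a smooth low-order radial
#' harmonic, `r(theta) <= 1 + amp * cos(k * theta + phase)` in normalised
#' elliptical radius, to emulate irregular bladder outlines.
#'
#' @param lengthMM,heightMM full diameters in mm (> 0).
#' @param spacingMM pixel size in mm (scalar, square pixels).
#' @param perturbAmp harmonic amplitude as a fraction of the radius
#'   (default 0 = exact ellipse; keep well below 1).
#' @param harmonic integer harmonic order k (>= 2 keeps the shape closed
#'   and smooth).
#' @param phase harmonic phase in radians.
#' @return a sagittal-view [PixelGrid2D-class].
#' @export
makeEllipseMask <- function(lengthMM, heightMM, spacingMM = 1,
                            perturbAmp = 0, harmonic = 2L, phase = 0) {
  if (lengthMM <= 0 || heightMM <= 0 || spacingMM <= 0)
    stop("diameters and spacing must be strictly positive")
  if (perturbAmp < 0 || perturbAmp >= 1)
    stop("perturbAmp must be in [0, 1)")
  s <- spacingMM
  # odd counts: centre the outline on a pixel centre (see makeEllipsoidPhantom);
  # the grid must also cover the outward excursion of the perturbation
  nr <- 2L * as.integer(ceiling(heightMM * (1 + perturbAmp) / (2 * s))) + 3L
  nc <- 2L * as.integer(ceiling(lengthMM * (1 + perturbAmp) / (2 * s))) + 3L
  yv <- ((seq_len(nr) - 0.5) * s - nr * s / 2) / (heightMM / 2)
  xv <- ((seq_len(nc) - 0.5) * s - nc * s / 2) / (lengthMM / 2)
  X <- matrix(xv, nr, nc, byrow = TRUE)
  Y <- matrix(yv, nr, nc)
  r <- sqrt(X^2 + Y^2)
  lim <- 1 + perturbAmp * cos(harmonic * atan2(Y, X) + phase)
  PixelGrid2D(matrix(as.integer(r <= lim), nr, nc), s, s, "sagittal")
}

#' Project a phantom to its transverse and sagittal view masks
#'
#' Emulates the sonographer's choice of the maximal bladder image in each
#' plane: selects the transverse (fixed-z) slice and the sagittal
#' (fixed-x) slice of maximal cross-sectional area, ties broken by the
#' slice closest to the volume centroid, then the smaller index. Pixel
#' spacings are inherited from the voxel spacing.
#'
#' @param phantom a nonempty [Phantom3D-class].
#' @param preprocess clean the projected masks? Default `TRUE` (harmless
#'   on the already-clean synthetic projections).
#' @return a [ViewPair-class].
#' @export
projectViews <- function(phantom, preprocess = TRUE) {
  stopifnot(is(phantom, "Phantom3D"))
  vox <- phantom@voxels
  if (sum(vox) == 0L)
    stop("cannot project an empty phantom")
  sp <- phantom@spacingMM   # (y, x, z)
  pick <- function(areas) {
    best <- which(areas == max(areas))
    if (length(best) > 1L) {
      centroid <- sum(seq_along(areas) * areas) / sum(areas)
      d <- abs(best - centroid)
      best <- min(best[d == min(d)])
    }
    best[1L]
  }
  zAreas <- apply(vox, 3L, sum)
  xAreas <- apply(vox, 2L, sum)
  kz <- pick(zAreas)
  kx <- pick(xAreas)
  tv <- PixelGrid2D(vox[, , kz], spacingColMM = sp[2L],
                    spacingRowMM = sp[1L], viewLabel = "transverse")
  sg <- PixelGrid2D(vox[, kx, ], spacingColMM = sp[3L],
                    spacingRowMM = sp[1L], viewLabel = "sagittal")
  ViewPair(tv, sg, preprocess = preprocess)
}

#' Export a phantom as a multi-page TIFF
#'
#' One page per transverse (fixed-z) slice, foreground white; for
#' inspection in external viewers.
#'
#' @param phantom a [Phantom3D-class].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
writePhantomTIFF <- function(phantom, path) {
  stopifnot(is(phantom, "Phantom3D"))
  pages <- lapply(seq_len(dim(phantom@voxels)[3L]),
                  function(k) phantom@voxels[, , k] * 1.0)
  tiff::writeTIFF(pages, where = path)
  invisible(path)
}
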