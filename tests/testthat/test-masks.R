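test_that("loadMask binarizes PNG and TIFF input and validates spacing", {
  m <- matrix(0, 4, 4)
  m[c(2, 6, 11, 16)] <- 1
  pngPath <- withr::local_tempfile(fileext = ".png")
  png::writePNG(m, pngPath)
  g <- loadMask(pngPath, 1, 1, "transverse")
  expect_equal(sum(pixelMatrix(g)), 4)
  expect_identical(viewLabel(g), "transverse")

  tifPath <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(m, tifPath)
  expect_equal(pixelMatrix(loadMask(tifPath, 1)), pixelMatrix(g))

  expect_error(loadMask(pngPath, 0, 1), "positive")
  expect_error(loadMask(pngPath, 1, -2), "positive")
  expect_error(loadMask(file.path(tempdir(), "nope.png"), 1), "not found")
})

test_that("RGB white-on-black masks binarize like their greyscale version", {
  m <- matrix(0, 6, 6)
  m[2:4, 3:5] <- 1
  rgb <- array(0, dim = c(6, 6, 3))
  for (k in 1:3) rgb[, , k] <- m
  pGray <- withr::local_tempfile(fileext = ".png")
  pRGB <- withr::local_tempfile(fileext = ".png")
  png::writePNG(m, pGray)
  png::writePNG(rgb, pRGB)
  expect_equal(pixelMatrix(loadMask(pRGB, 1)), pixelMatrix(loadMask(pGray, 1)))
})

test_that("preprocessMask keeps the largest 4-connected component and fills holes", {
  m <- matrix(0, 12, 12)
  m[2:3, 2:6] <- 1                      # 10 px component
  m[9, 9:11] <- 1                       # 3 px component
  out <- preprocessMask(PixelGrid2D(m, 1))
  expect_equal(sum(pixelMatrix(out)), 10)
  expect_equal(sum(pixelMatrix(out)[9, ]), 0)

  # a component connected only diagonally must not bridge
  m2 <- matrix(0, 6, 6)
  m2[2:3, 2:3] <- 1
  m2[4, 4] <- 1
  expect_equal(sum(pixelMatrix(preprocessMask(PixelGrid2D(m2, 1)))), 4)

  ring <- matrix(0, 7, 7)
  ring[2:6, 2:6] <- 1
  ring[3:5, 3:5] <- 0
  filled <- preprocessMask(PixelGrid2D(ring, 1))
  expect_equal(sum(pixelMatrix(filled)), 25)  # ring plus interior

  rect <- solidMask(4, 5)
  expect_equal(pixelMatrix(preprocessMask(rect)), pixelMatrix(rect))
  expect_error(preprocessMask(PixelGrid2D(matrix(0, 3, 3), 1)), "empty")
})

test_that("preprocessMask is idempotent on irregular masks", {
  for (seed in 1:5) {
    once <- preprocessMask(randomBlobMask(seed))
    twice <- preprocessMask(once)
    expect_equal(pixelMatrix(twice), pixelMatrix(once))
  }
})

test_that("measureExtents uses inclusive pixel counts times spacing", {
  rect <- solidMask(3, 5)
  expect_equal(measureExtents(rect),
               c(horizontal_mm = 5, vertical_mm = 3))
  rectHalf <- PixelGrid2D(matrix(1, 3, 5), 0.5)
  expect_equal(measureExtents(rectHalf),
               c(horizontal_mm = 2.5, vertical_mm = 1.5))
  single <- matrix(0, 5, 5); single[3, 3] <- 1
  expect_equal(unname(measureExtents(PixelGrid2D(single, 0.7))),
               c(0.7, 0.7))
  expect_error(measureExtents(PixelGrid2D(matrix(0, 2, 2), 1)), "empty")
})

test_that("measureExtents is invariant to translating the foreground", {
  set.seed(42)
  for (i in 1:5) {
    m <- matrix(0, 30, 30)
    m[5:12, 4:15] <- matrix(rbinom(96, 1, 0.7), 8)
    m[8, 9] <- 1
    ref <- measureExtents(PixelGrid2D(m, 0.3))
    shifted <- matrix(0, 30, 30)
    dr <- sample(-3:10, 1); dc <- sample(-2:12, 1)
    shifted[5:12 + dr, 4:15 + dc] <- m[5:12, 4:15]
    expect_equal(measureExtents(PixelGrid2D(shifted, 0.3)), ref)
  }
})

test_that("crossoverColumn picks the tallest column with deterministic ties", {
  # all-tie rectangle spanning columns 1..5: centre column, zero offset
  info <- crossoverColumn(solidMask(4, 5))
  expect_s4_class(info, "CrossoverInfo")
  expect_equal(info@columnIndex, 3L)
  expect_equal(info@xcMM, 0)

  # triangle with a unique tallest column
  tri <- matrix(0, 5, 5)
  for (j in 1:4) tri[(5 - j + 1):5, j] <- 1
  info2 <- crossoverColumn(PixelGrid2D(tri, 1))
  expect_equal(info2@columnIndex, 4L)

  expect_error(crossoverColumn(PixelGrid2D(matrix(0, 3, 3), 1)), "empty")
})

test_that("crossoverColumn of an odd-width symmetric mask has zero offset", {
  # a centre column exists only for odd widths; even widths have two tied
  # central columns and resolve to the left one by the smaller-index rule
  for (seed in 1:5) {
    set.seed(seed)
    half <- matrix(rbinom(60, 1, 0.6), 10, 6)
    half[, 6] <- 1   # nonempty centre region
    m <- cbind(half, half[, 6], half[, 6:1])
    info <- crossoverColumn(PixelGrid2D(m, 0.4))
    expect_equal(info@xcMM, 0)
  }
  even <- crossoverColumn(solidMask(3, 4, spacing = 0.4))
  expect_equal(even@xcMM, -0.2)   # left of the two tied central columns
})

test_that("PixelGrid2D enforces its invariants", {
  expect_error(PixelGrid2D(matrix(1, 2, 2), -1), "positive")
  expect_error(PixelGrid2D(matrix(1, 2, 2), 1, viewLabel = "axial"),
               "viewLabel")
  g <- PixelGrid2D(matrix(c(0, 255, 3, 0), 2), 1)
  expect_true(all(pixelMatrix(g) %in% c(0L, 1L)))
  expect_equal(sum(pixelMatrix(g)), 2)
})

test_that("spacing sidecars round-trip and are validated", {
  p <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(transverse = list(col_mm = 0.4, row_mm = 0.5),
                        sagittal = list(col_mm = 0.3, row_mm = 0.3)), p)
  sc <- readSpacingSidecar(p)
  expect_equal(sc$transverse$row_mm, 0.5)
  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(transverse = list(col_mm = 0.4)), bad)
  expect_error(readSpacingSidecar(bad), "sidecar")
})
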