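test_that("rasterized areas match analytic polygon areas", {
  geom <- pixelGeometry(1, 1)
  square <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
  tri <- rbind(c(0, 0), c(10, 0), c(0, 10))
  cs <- contourSet(list(list(index = 0L, polygons = list(square, tri))),
                   geom)
  # one polygon per slice to measure them separately
  rs <- rasterizeContours(contourSet(list(list(index = 0L,
          polygons = list(square))), geom), c(16, 16), 5L)
  areaSq <- sum(rs$mask) * pixelArea(rs$geometry)
  expect_equal(areaSq, 100, tolerance = 8 / 100)  # one fine-pixel band
  rt <- rasterizeContours(contourSet(list(list(index = 0L,
          polygons = list(tri))), geom), c(16, 16), 5L)
  areaTri <- sum(rt$mask) * pixelArea(rt$geometry)
  expect_lte(abs(areaTri - 50) / 50, 0.02 + 1e-9)
  # shoelace oracle agrees with the analytic constants
  expect_equal(polygonArea(square), 100)
  expect_equal(polygonArea(tri), 50)
})

test_that("rasterization error shrinks as the upsampling factor grows", {
  geom <- pixelGeometry(1, 1)
  poly <- rbind(c(1.3, 2.1), c(11.7, 1.4), c(13.2, 9.8), c(6.1, 12.9),
                c(0.8, 8.2))
  truth <- polygonArea(poly)
  errAt <- function(f) {
    r <- rasterizeContours(contourSet(list(list(index = 0L,
           polygons = list(poly))), geom), c(16, 16), f)
    abs(sum(r$mask) * pixelArea(r$geometry) - truth) / truth
  }
  expect_lt(errAt(5L), 0.05)
  expect_lt(errAt(11L), errAt(1L))
  # physical area is invariant to the factor up to discretization
  expect_lt(abs(errAt(3L)) + abs(errAt(7L)), 0.1)
})

test_that("rasterization is equivariant under integer vertex shifts", {
  geom <- pixelGeometry(1, 1)
  poly <- rbind(c(1.2, 1.7), c(6.9, 2.2), c(5.4, 7.3))
  r0 <- rasterizeContours(contourSet(list(list(index = 0L,
          polygons = list(poly))), geom), c(20, 20), 5L)
  shifted <- sweep(poly, 2, c(3, 2), "+")  # +3 in x (cols), +2 in y (rows)
  r1 <- rasterizeContours(contourSet(list(list(index = 0L,
          polygons = list(shifted))), geom), c(20, 20), 5L)
  expect_identical(r1$mask[(1:50) + 10, (1:50) + 15, 1],
                   r0$mask[1:50, 1:50, 1])
})

test_that("degenerate and out-of-bounds polygons are rejected by name", {
  geom <- pixelGeometry(1, 1)
  expect_error(contourSet(list(list(index = 0L,
    polygons = list(rbind(c(0, 0), c(1, 1)))))), "fewer than 3")
  cs <- contourSet(list(list(index = 0L,
    polygons = list(rbind(c(0, 0), c(30, 0), c(0, 30))))), geom)
  expect_error(rasterizeContours(cs, c(16, 16), 5L),
               class = "doeeValidationError")
  empty <- contourSet(list(), geom)
  r <- rasterizeContours(empty, c(8, 8), 5L)
  expect_false(any(r$mask))
})

test_that("self-intersecting polygons warn and resolve by even-odd", {
  bowtie <- rbind(c(0, 0), c(8, 8), c(8, 0), c(0, 8))
  cs <- contourSet(list(list(index = 0L, polygons = list(bowtie))),
                   pixelGeometry(1, 1))
  expect_warning(r <- rasterizeContours(cs, c(10, 10), 5L),
                 "self-intersecting")
  # even-odd excludes nothing catastrophic: two triangular lobes remain
  expect_gt(sum(r$mask), 0)
})

test_that("contour JSON round-trips losslessly and rejects bad schema", {
  geom <- pixelGeometry(0.94, 0.94)
  cs <- contourSet(list(
    list(index = 0L, polygons = list(rbind(c(0.1, 0.2), c(5.37, 0.11),
                                           c(sqrt(2), 4 / 3)))),
    list(index = 3L, polygons = list())), geom)
  f <- tempfile(fileext = ".json")
  writeContoursJSON(cs, f)
  back <- readContoursJSON(f)
  expect_equal(back@geometry@dx, 0.94, tolerance = 0)
  expect_equal(length(back@slices), 2L)
  expect_equal(back@slices[[1]]$polygons[[1]],
               cs@slices[[1]]$polygons[[1]], tolerance = 0)
  expect_identical(back@slices[[2]]$index, 3L)

  # empty contour set round-trips
  f2 <- tempfile(fileext = ".json")
  writeContoursJSON(contourSet(list(), geom), f2)
  expect_identical(length(readContoursJSON(f2)@slices), 0L)

  # two-vertex polygon and missing keys are schema errors
  writeLines('{"geometry": {"dx": 1, "dy": 1},
    "slices": [{"index": 0, "polygons": [[[0,0],[1,1]]]}]}', f2)
  expect_error(readContoursJSON(f2), class = "doeeSchemaError")
  writeLines('{"slices": []}', f2)
  expect_error(readContoursJSON(f2), "geometry",
               class = "doeeSchemaError")
  writeLines('{"geometry": {"dx": 1, "dy": 1}, not json', f2)
  expect_error(readContoursJSON(f2), class = "doeeSchemaError")
})

test_that("NIfTI masks round-trip with header geometry", {
  arr <- array(0L, c(12, 10, 3))
  arr[3:5, 4:6, 2] <- 1L
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(0.94, 0.94, 3)
  f <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, f)
  v <- readMaskVolume(f)
  expect_equal(v$geometry@dx, 0.94, tolerance = 1e-6)
  expect_equal(v$geometry@dy, 0.94, tolerance = 1e-6)
  expect_equal(sum(v$mask), 9)
  expect_identical(dim(v$mask), c(12L, 10L, 3L))

  # explicit geometry wins over the header with a warning
  expect_warning(v2 <- readMaskVolume(f, pixelGeometry(1, 1)),
                 "overridden")
  expect_equal(v2$geometry@dx, 1)

  # all-zero volume reads as all-false
  img0 <- RNifti::asNifti(array(0L, c(4, 4, 2)))
  f0 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img0, f0)
  expect_false(any(readMaskVolume(f0, pixelGeometry(1, 1))$mask))
})

test_that("pairing rejects shape mismatches and non-binary input", {
  m1 <- array(0, c(4, 4, 2)); m2 <- array(0, c(4, 5, 2))
  m1[1] <- 1; m2[1] <- 1
  expect_error(raterMaskPair(m1, m2), class = "doeePairingError")
  bad <- array(0, c(4, 4, 2)); bad[1] <- 2
  expect_error(raterMaskPair(bad, m1), "non-binary")
})

test_that("PNG slice stacks read with explicit geometry", {
  m <- matrix(0, 8, 8); m[2:3, 2:3] <- 1
  f1 <- tempfile(fileext = ".png"); f2 <- tempfile(fileext = ".png")
  png::writePNG(m, f1); png::writePNG(matrix(0, 8, 8), f2)
  v <- readMaskVolume(c(f1, f2), pixelGeometry(0.5, 0.5))
  expect_identical(dim(v$mask), c(8L, 8L, 2L))
  expect_equal(sum(v$mask), 4)
  expect_error(readMaskVolume(c(f1, f2)), "geometry")
})
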