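test_that("cumulative curve counts strictly-greater areas", {
  reg <- toyRegionSet()   # single-rater areas 1, 2, 3 (rater 1), 4 (rater 2)
  curve <- cumulativeDetectionCurve(reg)
  expect_equal(countAbove(curve, 3), 1)
  expect_equal(countAbove(curve, 2), 2)
  expect_equal(countAbove(curve, 0), 4)
  expect_equal(countAbove(curve, 4), 0)
  expect_equal(countAbove(curve, 2, rater = 1), 1)
  expect_equal(countAbove(curve, 2, rater = 2), 1)

  # areas {1,2,3}, all rater 1: counts 3,2,1,0 at thresholds 0,1,2,3
  reg13 <- reg[reg$label == "CR1", ]
  c13 <- cumulativeDetectionCurve(reg13)
  expect_equal(countAbove(c13, c(0, 1, 2, 3)), c(3, 2, 1, 0))

  # no single-rater regions: flat zero
  flat <- cumulativeDetectionCurve(reg[reg$label == "CR12", ])
  expect_equal(countAbove(flat, c(0, 5)), c(0, 0))
})

test_that("curve is non-increasing and decomposes by rater", {
  set.seed(5)
  for (i in 1:15) {
    reg <- partitionRegions(randomBlobPair())
    curve <- cumulativeDetectionCurve(reg)
    expect_true(all(diff(curve@total) <= 0))
    expect_equal(curve@total, curve@r1Only + curve@r2Only)
  }
  # normalization divides by the scan count
  reg <- toyRegionSet()
  cn <- cumulativeDetectionCurve(reg, normalized = TRUE, nScans = 2L)
  expect_equal(countAbove(cn, 0), 2)
  expect_error(cumulativeDetectionCurve(reg, normalized = TRUE,
                                        nScans = 0L),
               class = "doeeDomainError")
})

test_that("outline statistic is bounded and signed as documented", {
  reg <- data.frame(scan_id = "s", slice = 1L, label = "CR12",
                    area_union = 9, area_r1 = 6, area_r2 = 5,
                    area_intersection = 2, stringsAsFactors = FALSE)
  h <- outlineErrorDistribution(reg)
  expect_equal(h@values, -1 / 9)
  expect_identical(sum(h@counts), 1L)

  # identical pairs: all mass in the bin containing 0
  regId <- data.frame(scan_id = "s", slice = 1L, label = "CR12",
                      area_union = c(4, 7), area_r1 = c(4, 7),
                      area_r2 = c(4, 7), area_intersection = c(4, 7),
                      stringsAsFactors = FALSE)
  hId <- outlineErrorDistribution(regId)
  zeroBin <- findInterval(0, hId@breaks, rightmost.closed = TRUE)
  expect_identical(hId@counts[zeroBin], 2L)
  expect_identical(sum(hId@counts), 2L)

  set.seed(13)
  for (i in 1:15) {
    reg <- partitionRegions(randomBlobPair())
    if (!any(reg$label == "CR12")) next
    h <- outlineErrorDistribution(reg)
    expect_true(all(h@values >= -1 & h@values <= 1))
    expect_identical(sum(h@counts), sum(reg$label == "CR12"))
  }

  expect_warning(outlineErrorDistribution(regId[0, ]), "no CR12")
  expect_error(outlineErrorDistribution(regId, binWidth = 0.3),
               class = "doeeDomainError")
})

test_that("rater swap mirrors both diagnostic structures", {
  set.seed(29)
  pair <- randomBlobPair(nr = 40, nc = 40, nblobs = 5)
  swapped <- raterMaskPair(pair@rater2, pair@rater1, pair@geometry)
  reg <- partitionRegions(pair)
  regS <- partitionRegions(swapped)
  # statistic-level mirror is exact
  h <- outlineErrorDistribution(reg)
  hS <- outlineErrorDistribution(regS)
  expect_equal(sort(hS@values), sort(-h@values))
  # curve: rater roles exchange
  cu <- cumulativeDetectionCurve(reg)
  cuS <- cumulativeDetectionCurve(regS)
  expect_equal(cu@total, cuS@total)
  expect_equal(cu@r1Only, cuS@r2Only)
  expect_equal(cu@r2Only, cuS@r1Only)
  # count-level mirror on a fixture with no edge-valued statistics
  regF <- data.frame(scan_id = "f", slice = 1L, label = "CR12",
                     area_union = c(9, 11, 13), area_r1 = c(6, 3, 13),
                     area_r2 = c(5, 9, 9),
                     area_intersection = c(2, 1, 9),
                     stringsAsFactors = FALSE)
  regFswap <- regF
  regFswap$area_r1 <- regF$area_r2
  regFswap$area_r2 <- regF$area_r1
  hF <- outlineErrorDistribution(regF)
  hFs <- outlineErrorDistribution(regFswap)
  expect_identical(hFs@counts, rev(hF@counts))
})

test_that("graphs render to files and export deterministic tables", {
  reg <- toyRegionSet()
  curve <- cumulativeDetectionCurve(reg)
  h <- outlineErrorDistribution(reg)
  for (obj in list(curve, h)) {
    f <- tempfile(fileext = ".png")
    renderGraphs(obj, f)
    expect_true(file.exists(f))
    expect_gt(file.size(f), 0)
  }
  # empty histogram renders the placeholder without error
  hEmpty <- suppressWarnings(outlineErrorDistribution(reg[0, ]))
  f <- tempfile(fileext = ".png")
  renderGraphs(hEmpty, f)
  expect_true(file.exists(f))
  # TSV export is byte-deterministic for fixed input
  f1 <- tempfile(); f2 <- tempfile()
  writeGraphTable(curve, f1); writeGraphTable(curve, f2)
  expect_identical(readLines(f1), readLines(f2))
  tab <- read.delim(f1)
  expect_identical(names(tab), c("threshold", "total", "r1_only",
                                 "r2_only"))
})
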