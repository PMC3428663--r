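test_that("detection and outline errors reproduce the worked slice", {
  reg <- workedSliceRegions()
  expect_equal(detectionError(reg), 39.5)
  expect_equal(outlineError(reg), 141.1, tolerance = 1e-12)
  sa <- scanAgreement(reg)
  expect_equal(sa@MTA, 997.4, tolerance = 1e-12)
  expect_equal(sa@OER, 0.142, tolerance = 0.001 / 0.142)
  expect_identical(sa@nCR1, 2L)
})

test_that("error sums behave additively on simple tables", {
  reg <- toyRegionSet()
  expect_equal(detectionError(reg), 1 + 2 + 3 + 4)
  expect_equal(outlineError(reg), (10 - 7) + (8 - 5) + (12 - 9))
  expect_equal(detectionError(reg[0, ]), 0)
  expect_equal(outlineError(reg[0, ]), 0)
  # DE + OE equals OR-area minus AND-area, exactly, on pixel masks
  set.seed(3)
  for (i in 1:10) {
    pair <- randomBlobPair()
    reg <- partitionRegions(pair)
    expect_equal(detectionError(reg) + outlineError(reg),
                 sum(pair@rater1 | pair@rater2) -
                   sum(pair@rater1 & pair@rater2))
  }
})

test_that("agreement summary handles identity, disjoint and degenerate scans", {
  m <- matrix(FALSE, 8, 8); m[2:4, 2:4] <- TRUE
  sa <- scanAgreement(partitionRegions(raterMaskPair(m, m)))
  expect_equal(sa@SI, 1)
  expect_equal(sa@DE, 0)
  expect_equal(sa@OE, 0)
  expect_equal(sa@JI, 1)

  other <- matrix(FALSE, 8, 8); other[6:8, 6:8] <- TRUE
  sd <- scanAgreement(partitionRegions(raterMaskPair(m, other)))
  expect_equal(sd@SI, 0)
  expect_equal(sd@DE, 18)
  expect_equal(sd@OE, 0)
  expect_equal(sd@MTA, 9)

  empty <- matrix(FALSE, 8, 8)
  expect_error(scanAgreement(partitionRegions(raterMaskPair(empty, empty))),
               class = "doeeDegenerateScanError")
})

test_that("the two SI forms and the SI-JI relation agree on random pairs", {
  set.seed(11)
  for (i in 1:200) {
    pair <- if (i %% 2) randomMaskPair(p = runif(1, 0.05, 0.4))
            else randomBlobPair()
    reg <- partitionRegions(pair)
    if (sum(reg$area_r1) + sum(reg$area_r2) == 0) next
    sa <- scanAgreement(reg)
    siDecomp <- 1 - sa@OE / (2 * sa@MTA) - sa@DE / (2 * sa@MTA)
    expect_equal(sa@SI, siDecomp, tolerance = 1e-12)
    expect_equal(sa@SI, siFromJI(sa@JI), tolerance = 1e-12)
    expect_gte(sa@SI, sa@JI)
  }
})

test_that("metrics scale correctly with pixel geometry", {
  a <- matrix(FALSE, 10, 10); a[2:5, 2:5] <- TRUE
  b <- matrix(FALSE, 10, 10); b[4:7, 4:7] <- TRUE; b[9, 9] <- TRUE
  s1 <- scanAgreement(partitionRegions(raterMaskPair(a, b,
          pixelGeometry(1, 1))))
  s2 <- scanAgreement(partitionRegions(raterMaskPair(a, b,
          pixelGeometry(0.94, 0.94))))
  f <- 0.94^2
  expect_equal(s2@SI, s1@SI, tolerance = 1e-12)
  expect_equal(s2@JI, s1@JI, tolerance = 1e-12)
  expect_equal(s2@OER, s1@OER, tolerance = 1e-12)
  expect_equal(s2@DE, s1@DE * f, tolerance = 1e-12)
  expect_equal(s2@OE, s1@OE * f, tolerance = 1e-12)
  expect_equal(s2@MTA, s1@MTA * f, tolerance = 1e-12)
})

test_that("siEstimate follows the burden model and its limit", {
  # high-burden limit: 1 - meanOER/2
  expect_equal(siEstimate(746.8, 0.4077, 1e12), 1 - 0.4077 / 2,
               tolerance = 1e-6)
  expect_equal(siEstimate(746.8, 0.4077, 5028),
               1 - 0.20385 - 373.4 / 5028, tolerance = 1e-12)
  expect_equal(siEstimate(746.8, 0.4077, 848),
               0.3558, tolerance = 1e-4)
  expect_equal(siEstimate(0, 0, c(1, 10, 1000)), c(1, 1, 1))
  # honest about its domain: may go negative at tiny MTA, errors at 0
  expect_lt(siEstimate(746.8, 0.4077, 100), 0)
  expect_error(siEstimate(746.8, 0.4077, 0), class = "doeeDomainError")
})

test_that("SI-JI conversions are inverse bijections on [0, 1]", {
  expect_equal(siFromJI(c(0, 1)), c(0, 1))
  expect_equal(siFromJI(1 / 3), 0.5)
  expect_equal(jiFromSI(0.5), 1 / 3)
  x <- seq(0, 1, by = 0.01)
  expect_equal(jiFromSI(siFromJI(x)), x, tolerance = 1e-14)
  expect_equal(siFromJI(jiFromSI(x)), x, tolerance = 1e-14)
  expect_error(siFromJI(1.2), class = "doeeDomainError")
  expect_error(jiFromSI(-0.1), class = "doeeDomainError")
})

test_that("kappa converges monotonically to SI as background grows", {
  a <- matrix(FALSE, 12, 12); a[2:6, 2:6] <- TRUE     # 25 px
  b <- matrix(FALSE, 12, 12); b[4:8, 3:7] <- TRUE     # 25 px, overlap 15
  pair <- raterMaskPair(a, b)
  sa <- scanAgreement(partitionRegions(pair))
  unionPx <- sum(a | b)
  expect_error(kappaOnFrame(pair, unionPx - 1), class = "doeeDomainError")
  ks <- vapply(c(1, 2, 5, 10, 50, 200, 1000, 5000) * unionPx,
               function(n) kappaOnFrame(pair, n), 0)
  expect_true(all(diff(ks) > 0))
  expect_lt(abs(ks[length(ks)] - sa@SI), 0.001)
  # oracle: closed-form 2x2 table kappa at one frame size
  n11 <- sum(a & b); n10 <- sum(a & !b); n01 <- sum(!a & b)
  d <- 10 * unionPx; n <- n11 + n10 + n01 + d
  po <- (n11 + d) / n
  pe <- ((n11 + n10) * (n11 + n01) + (n01 + d) * (n10 + d)) / n^2
  expect_equal(kappaOnFrame(pair, d), (po - pe) / (1 - pe))

  # identical masks: kappa = 1 at any frame
  pid <- raterMaskPair(a, a)
  expect_equal(kappaOnFrame(pid, 1000), 1)
  # disjoint equal masks: kappa approaches 0 from below
  c2 <- matrix(FALSE, 12, 12); c2[9:11, 9:11] <- TRUE
  a3 <- matrix(FALSE, 12, 12); a3[2:4, 2:4] <- TRUE
  pd <- raterMaskPair(a3, c2)
  kd <- kappaOnFrame(pd, 10000)
  expect_lt(kd, 0)
  expect_gt(kd, -0.01)
})

test_that("study table round-trips through the TSV writer", {
  m <- matrix(FALSE, 8, 8); m[2:4, 2:4] <- TRUE
  sa <- scanAgreement(partitionRegions(raterMaskPair(m, m,
          scanId = "s1")))
  tab <- studyTable(list(sa))
  expect_identical(tab$scan_id, "s1")
  f <- tempfile(fileext = ".tsv")
  writeStudyTable(tab, f)
  back <- read.delim(f)
  expect_equal(back$SI, 1)
})
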