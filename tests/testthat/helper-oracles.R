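# Independent oracles and fixture builders used across test files.

# brute-force flood-fill connected-component labeling (queue-based)
floodLabel <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 8L) {
    dr <- c(-1, -1, -1, 0, 0, 1, 1, 1)
    dc <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  } else {
    dr <- c(-1, 1, 0, 0); dc <- c(0, 0, -1, 1)
  }
  cur <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    cur <- cur + 1L
    queue <- matrix(c(r0, c0), 1)
    lab[r0, c0] <- cur
    while (nrow(queue)) {
      p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (k in seq_along(dr)) {
        rr <- p[1] + dr[k]; cc <- p[2] + dc[k]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- cur
          queue <- rbind(queue, c(rr, cc))
        }
      }
    }
  }
  lab
}

# region table computed from a labeling, for comparison with
# partitionRegions (areas in pixel units: geometry 1 x 1 mm)
oracleRegions <- function(m1, m2, connectivity = 8L) {
  lab <- floodLabel(m1 | m2, connectivity)
  k <- max(lab)
  if (k == 0L) return(NULL)
  do.call(rbind, lapply(seq_len(k), function(i) {
    px <- lab == i
    a1 <- sum(px & m1); a2 <- sum(px & m2)
    data.frame(label = if (a1 > 0 && a2 > 0) "CR12"
               else if (a1 > 0) "CR1" else "CR2",
               area_union = as.numeric(sum(px)),
               area_r1 = as.numeric(a1), area_r2 = as.numeric(a2),
               area_intersection = as.numeric(sum(px & m1 & m2)))
  }))
}

# canonical sort for multiset comparison of region rows
sortRegions <- function(tab) {
  tab <- tab[, c("label", "area_union", "area_r1", "area_r2",
                 "area_intersection")]
  tab <- tab[order(tab$label, tab$area_union, tab$area_r1, tab$area_r2), ]
  rownames(tab) <- NULL
  tab
}

# random paired masks; guarantees at least one foreground pixel overall
randomMaskPair <- function(nr = 24, nc = 24, p = 0.15, scanId = "rand") {
  repeat {
    m1 <- matrix(runif(nr * nc) < p, nr, nc)
    m2 <- matrix(runif(nr * nc) < p, nr, nc)
    if (any(m1) || any(m2)) break
  }
  raterMaskPair(m1, m2, pixelGeometry(1, 1), scanId = scanId)
}

# blobby random pair: a few rectangles per rater (more lesion-like than
# iid noise, exercises CR12 regions)
randomBlobPair <- function(nr = 32, nc = 32, nblobs = 3, scanId = "blob") {
  paint <- function() {
    m <- matrix(FALSE, nr, nc)
    for (i in seq_len(nblobs)) {
      h <- sample(2:6, 1); w <- sample(2:6, 1)
      r <- sample(nr - h, 1); c <- sample(nc - w, 1)
      m[r:(r + h), c:(c + w)] <- TRUE
    }
    m
  }
  repeat {
    m1 <- paint(); m2 <- paint()
    if (any(m1) || any(m2)) break
  }
  raterMaskPair(m1, m2, pixelGeometry(1, 1), scanId = scanId)
}

# region table mimicking the worked single-slice example: matched lesion
# pairs are nested (intersection = smaller area, union = larger), plus
# two single-rater lesions
workedSliceRegions <- function() {
  pairs <- rbind(c(106.7, 131.8), c(58.0, 58.0), c(32.1, 32.1),
                 c(27.7, 27.7), c(174.7, 224.0), c(507.9, 574.6))
  shared <- data.frame(scan_id = "fig", slice = 1L, label = "CR12",
                       area_union = pmax(pairs[, 1], pairs[, 2]),
                       area_r1 = pairs[, 1], area_r2 = pairs[, 2],
                       area_intersection = pmin(pairs[, 1], pairs[, 2]),
                       stringsAsFactors = FALSE)
  single <- data.frame(scan_id = "fig", slice = 1L,
                       label = c("CR1", "CR1"),
                       area_union = c(10.6, 28.9),
                       area_r1 = c(10.6, 28.9), area_r2 = c(0, 0),
                       area_intersection = c(0, 0),
                       stringsAsFactors = FALSE)
  rbind(shared, single)
}

# toy region set with the caption's cumulative structure: four
# single-rater regions (areas 1, 2, 3, 4; three from rater 1, one from
# rater 2) and three shared regions
toyRegionSet <- function() {
  single <- data.frame(scan_id = "toy", slice = 1L,
                       label = c("CR1", "CR1", "CR1", "CR2"),
                       area_union = c(1, 2, 3, 4),
                       area_r1 = c(1, 2, 3, 0),
                       area_r2 = c(0, 0, 0, 4),
                       area_intersection = c(0, 0, 0, 0),
                       stringsAsFactors = FALSE)
  shared <- data.frame(scan_id = "toy", slice = 1L, label = "CR12",
                       area_union = c(10, 8, 12),
                       area_r1 = c(9, 6, 10), area_r2 = c(8, 7, 11),
                       area_intersection = c(7, 5, 9),
                       stringsAsFactors = FALSE)
  rbind(single, shared)
}

# small fast generator config for pipeline tests
smallConfig <- function(nScans = 6L, seed = 1L, ...) {
  syntheticConfig(seed = seed, nScans = nScans, sliceShape = c(64L, 64L),
                  slicesPerScan = 6L, lesionCountMean = 10,
                  mtaRange = c(300, 2000), ...)
}
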