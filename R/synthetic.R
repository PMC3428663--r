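# Default mapping from requested mean OER (jitterStrength) to the sd of
# the per-lesion log radial perturbation. First-order analysis of the
# concentric-scaling model: with per-rater area factor exp(2*eps),
# eps ~ N(-sigma^2, sigma^2), the expected per-lesion |union - inter| /
# mean-area is ~ (4/sqrt(pi)) * sigma, so sigma ~ strength / 2.26;
# boundary discretization on small lesions adds outline disagreement, so
# the constant is set by the included calibration routine
# (calibrateJitter) run at the default configuration.
.jitterK <- 2.07

#' Configure the paired-segmentation generator
#'
#' Defaults emulate the statistical structure of a two-rater FLAIR MS
#' lesion study: 17 scans, in-plane pixels 0.94 x 0.94 mm, per-scan lesion
#' burden (MTA) spanning 848-17996 mm^2 log-uniformly, detection
#' disagreement concentrated on small lesions and roughly constant across
#' burden, outline disagreement proportional to burden with a mean OER
#' near 0.4.
#'
#' @param seed integer seed; the whole study is reproducible from it
#' @param nScans number of scans
#' @param sliceShape (rows, cols) of each slice
#' @param slicesPerScan slices per scan
#' @param lesionCountMean Poisson mean of the per-scan count of small
#'   "ambiguous" lesions (the pool carrying the detection-miss risk)
#' @param lesionAreaMeanlog,lesionAreaSdlog lognormal (meanlog, sdlog) of
#'   ambiguous-lesion areas, mm^2
#' @param burdenAreaMeanlog,burdenAreaSdlog lognormal parameters of the
#'   burden-pool lesion areas, mm^2; burden lesions are added until their
#'   total tracks the scan's target MTA
#' @param missA,missB logistic miss model: a rater omits a lesion of area
#'   A mm^2 with probability plogis(missA - missB * log(A)), independently
#'   per lesion and rater, so small lesions are missed more often
#' @param jitterStrength target mean Outline Error Rate; detected outlines
#'   are scaled radially by exp(eps), eps ~ N(-sigma^2, sigma^2) with
#'   sigma calibrated to this target (see \code{\link{calibrateJitter}})
#' @param geometry in-plane \linkS4class{PixelGeometry}
#' @param mtaRange (low, high) mm^2; per-scan target MTA is log-uniform
#' @return a \linkS4class{SyntheticConfig}
#' @export
syntheticConfig <- function(seed = 1L, nScans = 17L,
                            sliceShape = c(128L, 128L),
                            slicesPerScan = 20L, lesionCountMean = 120,
                            lesionAreaMeanlog = log(12),
                            lesionAreaSdlog = 0.5,
                            burdenAreaMeanlog = log(250),
                            burdenAreaSdlog = 0.7,
                            missA = 10.43, missB = 3.5,
                            jitterStrength = 0.4,
                            geometry = pixelGeometry(0.94, 0.94),
                            mtaRange = c(848, 17996)) {
  new("SyntheticConfig", seed = as.integer(seed), nScans = as.integer(nScans),
      sliceShape = as.integer(sliceShape),
      slicesPerScan = as.integer(slicesPerScan),
      lesionCountMean = lesionCountMean,
      lesionAreaMeanlog = lesionAreaMeanlog,
      lesionAreaSdlog = lesionAreaSdlog,
      burdenAreaMeanlog = burdenAreaMeanlog,
      burdenAreaSdlog = burdenAreaSdlog,
      missA = missA, missB = missB, jitterStrength = jitterStrength,
      geometry = geometry, mtaRange = as.numeric(mtaRange))
}

#' @export
setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf(
    "SyntheticConfig: %d scan(s), %d x %d x %d, MTA target %g-%g mm^2\n",
    object@nScans, object@sliceShape[1], object@sliceShape[2],
    object@slicesPerScan, object@mtaRange[1], object@mtaRange[2]))
  cat(sprintf("  ambiguous pool: ~Pois(%g) lesions, LN(%.2f, %.2f) mm^2\n",
              object@lesionCountMean, object@lesionAreaMeanlog,
              object@lesionAreaSdlog))
  cat(sprintf("  miss model plogis(%.2f - %.2f log A); jitter target OER %.2f\n",
              object@missA, object@missB, object@jitterStrength))
})

missProbability <- function(area, missA, missB) stats::plogis(missA - missB * log(area))

# paint an ellipse (pixel-center test) onto a logical matrix, in place
paintEllipse <- function(mask, cx, cy, a, b, theta) {
  nr <- nrow(mask); nc <- ncol(mask)
  rmax <- max(a, b)
  ci <- max(1L, floor(cx - rmax) + 1L):min(nc, ceiling(cx + rmax) + 1L)
  ri <- max(1L, floor(cy - rmax) + 1L):min(nr, ceiling(cy + rmax) + 1L)
  x <- ci - 1; y <- ri - 1
  dxm <- matrix(x, length(ri), length(ci), byrow = TRUE) - cx
  dym <- matrix(y, length(ri), length(ci)) - cy
  u <- dxm * cos(theta) + dym * sin(theta)
  v <- -dxm * sin(theta) + dym * cos(theta)
  mask[ri, ci] <- mask[ri, ci] | ((u / a)^2 + (v / b)^2 <= 1)
  mask
}

#' Generate a synthetic two-rater segmentation study
#'
#' For each scan, samples a target lesion burden (MTA) log-uniformly over
#' the configured range and realizes it as random rotated ellipses on
#' random slices: a burden pool of larger lesions whose total truth area
#' matches the target, plus a fixed-rate pool of small ambiguous lesions.
#' Each rater independently omits each lesion with the area-dependent
#' logistic miss probability, and draws each kept lesion with its
#' semi-axes scaled by exp(eps), eps ~ N(-sigma^2, sigma^2) (unit mean
#' area factor), sigma calibrated so the study mean OER approximates
#' \code{jitterStrength}. Lesions that cannot be placed inside the slice
#' after 100 attempts raise an error. Fully reproducible from the seed.
#'
#' @param config a \linkS4class{SyntheticConfig}
#' @param seed overrides \code{config@seed} when given
#' @return list with \code{pairs} (list of \linkS4class{RaterMaskPair}),
#'   \code{lesions} (per-lesion truth table: scan_id, slice, pool,
#'   area_mm2, s1, s2, miss1, miss2), \code{scans} (per-scan targets),
#'   \code{jitterSigma} and \code{config}
#' @export
generateStudy <- function(config, seed = NULL) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  set.seed(if (is.null(seed)) config@seed else as.integer(seed))
  sigma <- config@jitterStrength / .jitterK
  nr <- config@sliceShape[1]; nc <- config@sliceShape[2]
  pa <- pixelArea(config@geometry)
  pairs <- vector("list", config@nScans)
  lesionTabs <- vector("list", config@nScans)
  targets <- numeric(config@nScans)
  for (sc in seq_len(config@nScans)) {
    target <- exp(stats::runif(1, log(config@mtaRange[1]),
                               log(config@mtaRange[2])))
    targets[sc] <- target
    nSmall <- stats::rpois(1, config@lesionCountMean)
    smallAreas <- if (nSmall > 0)
      stats::rlnorm(nSmall, config@lesionAreaMeanlog, config@lesionAreaSdlog)
    else numeric(0)
    # the burden pool covers whatever the ambiguous pool is not expected
    # to realize (misses remove area, so weight by detection probability)
    pSmall <- missProbability(smallAreas, config@missA, config@missB)
    burdenTarget <- max(0, target - sum(smallAreas * (1 - pSmall)))
    burdenAreas <- numeric(0)
    while (sum(burdenAreas) < burdenTarget)
      burdenAreas <- c(burdenAreas,
                       stats::rlnorm(8, config@burdenAreaMeanlog,
                                     config@burdenAreaSdlog))
    if (length(burdenAreas)) {
      keep <- which(cumsum(burdenAreas) < burdenTarget)
      burdenAreas <- burdenAreas[c(keep, length(keep) + 1L)]
      burdenAreas <- burdenAreas * (burdenTarget / sum(burdenAreas))
    }
    areas <- c(smallAreas, burdenAreas)
    pool <- rep(c("ambiguous", "burden"),
                c(length(smallAreas), length(burdenAreas)))
    nles <- length(areas)
    m1 <- array(FALSE, c(nr, nc, config@slicesPerScan))
    m2 <- array(FALSE, c(nr, nc, config@slicesPerScan))
    # lesions are distinct structures: their (jittered) footprints never
    # overlap, so a small lesion cannot be swallowed by a large one.
    # Largest first so big lesions find room before the slices fill up.
    occupied <- array(FALSE, c(nr, nc, config@slicesPerScan))
    ord <- order(areas, decreasing = TRUE)
    rec <- vector("list", nles)
    for (i in ord) {
      aPx <- areas[i] / pa
      ok <- FALSE
      for (attempt in 1:100) {
        slice <- sample.int(config@slicesPerScan, 1)
        q <- stats::runif(1, 0.4, 1)
        ax <- sqrt(aPx / (pi * q)); bx <- q * ax
        theta <- stats::runif(1, 0, pi)
        s12 <- exp(stats::rnorm(2, -sigma^2, sigma))
        guard <- max(ax, bx) * max(s12, 1) + 1
        if (2 * guard >= min(nr, nc) - 1) next
        cx <- stats::runif(1, guard, nc - 1 - guard)
        cy <- stats::runif(1, guard, nr - 1 - guard)
        foot <- paintEllipse(matrix(FALSE, nr, nc), cx, cy,
                             max(ax * s12, ax) + 0.5,
                             max(bx * s12, bx) + 0.5, theta)
        if (!any(foot & occupied[, , slice])) {
          occupied[, , slice] <- occupied[, , slice] | foot
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop(sprintf("lesion of %.0f mm^2 cannot be placed on a %d x %d slice",
                     areas[i], nr, nc), call. = FALSE)
      pm <- missProbability(areas[i], config@missA, config@missB)
      miss <- stats::runif(2) < pm
      if (!miss[1])
        m1[, , slice] <- paintEllipse(m1[, , slice], cx, cy,
                                      ax * s12[1], bx * s12[1], theta)
      if (!miss[2])
        m2[, , slice] <- paintEllipse(m2[, , slice], cx, cy,
                                      ax * s12[2], bx * s12[2], theta)
      rec[[i]] <- data.frame(scan_id = sprintf("synth%02d", sc),
                             slice = slice, pool = pool[i],
                             area_mm2 = areas[i], s1 = s12[1], s2 = s12[2],
                             miss1 = miss[1], miss2 = miss[2],
                             stringsAsFactors = FALSE)
    }
    pairs[[sc]] <- raterMaskPair(m1, m2, config@geometry,
                                 scanId = sprintf("synth%02d", sc))
    lesionTabs[[sc]] <- do.call(rbind, rec)
  }
  lesions <- do.call(rbind, lesionTabs)
  rownames(lesions) <- NULL
  list(pairs = pairs, lesions = lesions,
       scans = data.frame(scan_id = sprintf("synth%02d", seq_len(config@nScans)),
                          target_mta = targets, stringsAsFactors = FALSE),
       jitterSigma = sigma, config = config)
}

#' Calibrate the outline-jitter mapping
#'
#' Generates a study at the given configuration, measures the realized
#' mean Outline Error Rate, and reports the multiplicative correction the
#' sigma mapping would need to hit the requested \code{jitterStrength}
#' exactly. Used once to fix the default strength-to-sigma constant.
#'
#' @param config a \linkS4class{SyntheticConfig}
#' @param nScans number of scans to simulate (overrides config)
#' @param seed simulation seed
#' @return list: realized meanOER, target, suggested sigma scale factor
#' @export
calibrateJitter <- function(config = syntheticConfig(), nScans = 50L,
                            seed = 1L) {
  cfg <- config
  cfg@nScans <- as.integer(nScans)
  study <- generateStudy(cfg, seed = seed)
  oer <- vapply(study$pairs, function(p)
    scanAgreement(partitionRegions(p))@OER, 0)
  realized <- mean(oer)
  list(realizedOER = realized, target = cfg@jitterStrength,
       sigmaScale = cfg@jitterStrength / realized,
       suggestedK = .jitterK * realized / cfg@jitterStrength)
}

#' Forward-simulate an (MTA, SI) table from the burden model
#'
#' Samples MTA log-uniformly, predicts SI = 1 - meanOER/2 -
#' meanDE/(2 MTA), adds Gaussian noise and clamps to [0, 1]. Used to test
#' model fitting and selection without going through image masks.
#'
#' @param meanDE mean Detection Error, mm^2 (>= 0)
#' @param meanOER mean Outline Error Rate (in [0, 2])
#' @param n number of scans
#' @param noiseSd Gaussian sd of the SI noise
#' @param mtaRange (low, high) mm^2
#' @param seed optional seed
#' @return data.frame with columns MTA, SI
#' @export
generateSiMtaTable <- function(meanDE, meanOER, n = 17L, noiseSd = 0.05,
                               mtaRange = c(848, 17996), seed = NULL) {
  if (meanDE < 0 || meanOER < 0 || meanOER > 2)
    stopDoee("need meanDE >= 0 and meanOER in [0, 2]", "doeeDomainError")
  if (!is.null(seed)) set.seed(as.integer(seed))
  mta <- exp(stats::runif(n, log(mtaRange[1]), log(mtaRange[2])))
  siTrue <- siEstimate(meanDE, meanOER, mta)
  if (all(siTrue < 0))
    stop("parameters give negative SI over the whole MTA range",
         call. = FALSE)
  si <- pmin(1, pmax(0, siTrue + stats::rnorm(n, 0, noiseSd)))
  data.frame(MTA = mta, SI = si)
}

#' Write a generated study to disk
#'
#' One NIfTI mask volume per rater per scan (pixel geometry in the
#' header), a manifest TSV (scan_id, rater1_path, rater2_path) consumable
#' by \code{\link{cmdScore}}, and the ground truth as JSON.
#'
#' @param study result of \code{\link{generateStudy}}
#' @param dir output directory (created if needed)
#' @return the manifest path, invisibly
#' @export
writeSyntheticStudy <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(study$pairs, function(p) {
    f1 <- file.path(dir, sprintf("%s_rater1.nii.gz", p@scanId))
    f2 <- file.path(dir, sprintf("%s_rater2.nii.gz", p@scanId))
    writeMaskNifti(p@rater1, p@geometry, f1)
    writeMaskNifti(p@rater2, p@geometry, f2)
    data.frame(scan_id = p@scanId, rater1_path = f1, rater2_path = f2,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  manifestPath <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, manifestPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- list(jitter_sigma = study$jitterSigma,
                scans = study$scans, lesions = study$lesions)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifestPath)
}

# write a logical stack as uint8 NIfTI with in-plane pixdim set
writeMaskNifti <- function(mask, geometry, path) {
  img <- RNifti::asNifti(array(as.integer(mask), dim(mask)))
  RNifti::pixdim(img) <- c(geometry@dx, geometry@dy, 1)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}
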