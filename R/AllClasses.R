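#' @import methods
NULL

#' In-plane pixel geometry
#'
#' Physical size of one image pixel in millimetres. The analysis is
#' two-dimensional (per slice), so only the in-plane dimensions are carried;
#' slice thickness never enters any area computation.
#'
#' @slot dx pixel width in mm (> 0)
#' @slot dy pixel height in mm (> 0)
#' @export
setClass("PixelGeometry",
  representation(dx = "numeric", dy = "numeric"),
  validity = function(object) {
    if (length(object@dx) != 1L || length(object@dy) != 1L)
      return("dx and dy must be scalars")
    if (!is.finite(object@dx) || !is.finite(object@dy))
      return("dx and dy must be finite")
    if (object@dx <= 0 || object@dy <= 0)
      return("pixel dimensions must be positive")
    TRUE
  }
)

#' Per-slice closed-polygon contour set
#'
#' Format-neutral container for closed-path lesion outlines: each slice
#' record holds a non-negative slice index and a list of polygons, each an
#' n x 2 matrix of (x, y) vertices in 0-based pixel coordinates
#' (x = column, y = row, vertex-on-pixel-center convention). Polygons are
#' implicitly closed: the last vertex connects back to the first.
#'
#' @slot slices list of records, each \code{list(index =, polygons = )}
#' @slot geometry a \linkS4class{PixelGeometry}
#' @export
setClass("ContourSet",
  representation(slices = "list", geometry = "PixelGeometry"),
  validity = function(object) {
    for (sl in object@slices) {
      if (!is.list(sl) || is.null(sl$index) || is.null(sl$polygons))
        return("each slice record needs fields 'index' and 'polygons'")
      if (length(sl$index) != 1L || sl$index < 0 || sl$index != round(sl$index))
        return("slice index must be a single non-negative integer")
      for (p in sl$polygons) {
        if (!is.matrix(p) || ncol(p) != 2L || !is.numeric(p))
          return("each polygon must be a numeric n x 2 matrix")
        if (nrow(p) < 3L)
          return("polygon has fewer than 3 vertices")
        if (any(!is.finite(p)))
          return("polygon vertices must be finite")
      }
    }
    TRUE
  }
)

#' Paired binary mask stacks from two raters
#'
#' Aligned lesion masks for one scan: two logical arrays of identical
#' dimension (rows x cols x slices), plus the pixel geometry and an opaque
#' scan identifier. Construct with \code{\link{raterMaskPair}}, which
#' accepts numeric 0/1 input and enforces strict binarity.
#'
#' @slot rater1,rater2 logical arrays, rows x cols x slices
#' @slot geometry a \linkS4class{PixelGeometry}
#' @slot scanId character scalar
#' @export
setClass("RaterMaskPair",
  representation(rater1 = "array", rater2 = "array",
                 geometry = "PixelGeometry", scanId = "character"),
  validity = function(object) {
    d1 <- dim(object@rater1); d2 <- dim(object@rater2)
    if (length(d1) != 3L || length(d2) != 3L)
      return("mask stacks must be 3-dimensional (rows x cols x slices)")
    if (!identical(d1, d2))
      return("rater mask stacks have different shapes")
    if (!is.logical(object@rater1) || !is.logical(object@rater2))
      return("mask stacks must be logical")
    if (anyNA(object@rater1) || anyNA(object@rater2))
      return("mask stacks must not contain NA")
    if (length(object@scanId) != 1L)
      return("scanId must be a single string")
    TRUE
  }
)

#' Per-scan agreement summary
#'
#' Holds the detection/outline decomposition for one scan: mean total area
#' MTA = (|R1| + |R2|)/2, Detection Error DE (total area of single-rater
#' regions), Outline Error OE (union-minus-intersection area over shared
#' regions), OER = OE/MTA, the Similarity (Dice) Index, the Jaccard Index,
#' and the region counts by class.
#'
#' @slot scanId character
#' @slot MTA,DE,OE,OER,SI,JI numeric scalars (areas in mm^2)
#' @slot nCR1,nCR2,nCR12 integer region counts
#' @export
setClass("ScanAgreement",
  representation(scanId = "character", MTA = "numeric", DE = "numeric",
                 OE = "numeric", OER = "numeric", SI = "numeric",
                 JI = "numeric", nCR1 = "integer", nCR2 = "integer",
                 nCR12 = "integer"),
  validity = function(object) {
    if (object@MTA <= 0) return("MTA must be positive")
    if (object@DE < 0 || object@OE < 0) return("DE and OE must be >= 0")
    if (object@SI < -1e-12 || object@SI > 1 + 1e-12)
      return("SI out of [0, 1]")
    if (object@JI > object@SI + 1e-12) return("JI must not exceed SI")
    TRUE
  }
)

#' Study-level model comparison of SI versus lesion burden
#'
#' Result of \code{\link{fitStudy}}: the per-scan table, the mean Detection
#' Error and mean Outline Error Rate, the four competing models of SI as a
#' function of MTA (constant mean, linear, quadratic, and the
#' detection/outline decomposition SI = 1 - OER/2 - DE/(2 MTA)) with their
#' parameters, residual sums of squares, finite-sample-corrected AICc and
#' relative likelihoods, plus the correlation battery when the per-scan
#' table carries DE/OE/OER columns.
#'
#' @slot perScan data.frame with at least MTA and SI columns
#' @slot meanDE,meanOER numeric scalars
#' @slot models data.frame: model, k, rss, aicc, rel_likelihood
#' @slot params named list of per-model parameter vectors
#' @slot correlations data.frame: pair, method, estimate, p_value
#' @slot doeeFitMethod "means" or "least-squares"
#' @export
setClass("StudyFit",
  representation(perScan = "data.frame", meanDE = "numeric",
                 meanOER = "numeric", models = "data.frame",
                 params = "list", correlations = "data.frame",
                 doeeFitMethod = "character")
)

#' Cumulative Detection Error curve
#'
#' Step function answering: how many regions were marked by only one rater
#' with area strictly greater than a given threshold? Stored with the raw
#' single-rater region areas so the curve can be evaluated at any
#' threshold; optionally normalized to a per-scan average.
#'
#' @slot areas numeric, areas (mm^2) of all single-rater regions
#' @slot rater integer, 1 or 2, parallel to \code{areas}
#' @slot thresholds numeric, evaluation grid (0 and each distinct area)
#' @slot total,r1Only,r2Only counts (per-scan averages when normalized)
#' @slot normalized logical; nScans integer divisor used
#' @export
setClass("CumulativeCurve",
  representation(areas = "numeric", rater = "integer",
                 thresholds = "numeric", total = "numeric",
                 r1Only = "numeric", r2Only = "numeric",
                 normalized = "logical", nScans = "integer"),
  validity = function(object) {
    if (length(object@total) && any(diff(object@total) > 1e-9))
      return("total counts must be non-increasing in threshold")
    if (length(object@total) &&
        max(abs(object@total - object@r1Only - object@r2Only)) > 1e-9)
      return("total must equal r1Only + r2Only at every threshold")
    TRUE
  }
)

#' Outline Error Distribution histogram
#'
#' Histogram over shared (both-rater) regions of the signed relative area
#' difference (|R2| - |R1|) / |R1 u R2|, which always lies in [-1, 1].
#' Negative values mean rater 1 drew the larger outline. Bins are
#' half-open [lo, hi) over [-1, 1] with the last bin closed at 1.
#'
#' @slot breaks numeric bin edges spanning [-1, 1]
#' @slot counts integer counts per bin
#' @slot values numeric raw statistic values
#' @slot binWidth numeric
#' @export
setClass("OutlineHistogram",
  representation(breaks = "numeric", counts = "integer",
                 values = "numeric", binWidth = "numeric"),
  validity = function(object) {
    if (length(object@counts) != length(object@breaks) - 1L)
      return("counts must have one fewer entry than breaks")
    if (sum(object@counts) != length(object@values))
      return("histogram counts must sum to the number of statistic values")
    TRUE
  }
)

#' Configuration of the paired-segmentation generator
#'
#' Parameters of the synthetic study generator (see
#' \code{\link{generateStudy}}). Scan lesion burden is drawn log-uniformly
#' over \code{mtaRange}; each scan carries a burden pool of large lesions
#' whose total area tracks the target MTA, plus an "ambiguous" pool of
#' small lesions (count ~ Poisson(\code{lesionCountMean}), areas lognormal
#' with \code{lesionAreaMeanlog}/\code{lesionAreaSdlog}) that carries most
#' of the detection-miss risk. A rater omits a lesion of area A (mm^2) with
#' probability plogis(missA - missB * log(A)); detected outlines are
#' perturbed radially with strength calibrated so the study mean OER is
#' approximately \code{jitterStrength}.
#'
#' @export
setClass("SyntheticConfig",
  representation(seed = "integer", nScans = "integer",
                 sliceShape = "integer", slicesPerScan = "integer",
                 lesionCountMean = "numeric",
                 lesionAreaMeanlog = "numeric", lesionAreaSdlog = "numeric",
                 burdenAreaMeanlog = "numeric", burdenAreaSdlog = "numeric",
                 missA = "numeric", missB = "numeric",
                 jitterStrength = "numeric", geometry = "PixelGeometry",
                 mtaRange = "numeric"),
  validity = function(object) {
    if (object@nScans < 1L) return("nScans must be >= 1")
    if (length(object@sliceShape) != 2L || any(object@sliceShape < 8L))
      return("sliceShape must be two integers >= 8")
    if (object@slicesPerScan < 1L) return("slicesPerScan must be >= 1")
    if (object@lesionCountMean < 0) return("lesionCountMean must be >= 0")
    if (object@jitterStrength < 0) return("jitterStrength must be >= 0")
    if (length(object@mtaRange) != 2L || object@mtaRange[1] <= 0 ||
        object@mtaRange[1] >= object@mtaRange[2])
      return("mtaRange must be (low, high) with 0 < low < high")
    TRUE
  }
)
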