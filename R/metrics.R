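#' Detection Error
#'
#' Total area of regions marked by only one rater: the part of the
#' disagreement that is about whether a lesion exists at all. By
#' construction a region contributes to either the Detection Error or the
#' Outline Error, never both — its class alone routes it to one sum.
#'
#' @param regions a region table from \code{\link{partitionRegions}}
#' @return DE in mm^2 (0 for an empty table)
#' @export
detectionError <- function(regions) {
  checkRegionTable(regions)
  sum(regions$area_union[regions$label %in% c("CR1", "CR2")])
}

#' Outline Error
#'
#' Summed union-minus-intersection area over regions detected by both
#' raters: the part of the disagreement that is about where the boundary
#' of a jointly detected lesion lies.
#'
#' @param regions a region table from \code{\link{partitionRegions}}
#' @return OE in mm^2 (0 for an empty table)
#' @export
outlineError <- function(regions) {
  checkRegionTable(regions)
  i <- regions$label == "CR12"
  sum(regions$area_union[i] - regions$area_intersection[i])
}

#' Per-scan agreement summary
#'
#' Computes MTA, DE, OE, OER = OE/MTA, the Similarity (Dice) Index and the
#' Jaccard Index for one scan's region table. SI is computed both as
#' intersection/MTA and through the identity SI = 1 - OE/(2 MTA) -
#' DE/(2 MTA); the two must agree to 1e-12 relative tolerance (they are
#' algebraically identical) and the intersection form is stored.
#'
#' @param regions a region table for a single scan
#' @param scanId optional scan label; defaults to the table's scan_id
#' @return a \linkS4class{ScanAgreement}
#' @export
scanAgreement <- function(regions, scanId = NULL) {
  checkRegionTable(regions)
  if (is.null(scanId)) {
    ids <- unique(regions$scan_id)
    if (length(ids) > 1L)
      stop("region table spans several scans; pass one scan at a time",
           call. = FALSE)
    scanId <- if (length(ids)) ids else "scan"
  }
  a1 <- sum(regions$area_r1); a2 <- sum(regions$area_r2)
  mta <- (a1 + a2) / 2
  if (mta <= 0)
    stopDoee("degenerate scan: both raters' masks are empty (MTA = 0)",
             "doeeDegenerateScanError")
  de <- detectionError(regions)
  oe <- outlineError(regions)
  inter <- sum(regions$area_intersection)
  uni <- sum(regions$area_union)
  si1 <- inter / mta
  si5 <- 1 - oe / (2 * mta) - de / (2 * mta)
  if (abs(si1 - si5) > 1e-12 * max(1, abs(si1)))
    stop(sprintf("internal inconsistency: SI forms disagree (%.15g vs %.15g)",
                 si1, si5), call. = FALSE)
  cnt <- regionCounts(regions)
  new("ScanAgreement", scanId = as.character(scanId), MTA = mta, DE = de,
      OE = oe, OER = oe / mta, SI = si1,
      JI = if (uni > 0) inter / uni else 1,
      nCR1 = unname(cnt["CR1"]), nCR2 = unname(cnt["CR2"]),
      nCR12 = unname(cnt["CR12"]))
}

#' @export
setMethod("show", "ScanAgreement", function(object) {
  cat(sprintf("ScanAgreement '%s'\n", object@scanId))
  cat(sprintf("  MTA = %.1f mm^2, DE = %.1f mm^2, OE = %.1f mm^2\n",
              object@MTA, object@DE, object@OE))
  cat(sprintf("  OER = %.3f, SI = %.3f, JI = %.3f\n",
              object@OER, object@SI, object@JI))
  cat(sprintf("  regions: %d CR1, %d CR2, %d CR12\n",
              object@nCR1, object@nCR2, object@nCR12))
})

#' @export
setMethod("as.data.frame", "ScanAgreement",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(scan_id = x@scanId, MTA = x@MTA, DE = x@DE, OE = x@OE,
               OER = x@OER, SI = x@SI, JI = x@JI, n_cr1 = x@nCR1,
               n_cr2 = x@nCR2, n_cr12 = x@nCR12,
               stringsAsFactors = FALSE)
  })

#' Combine per-scan summaries into a study table
#'
#' @param scans list of \linkS4class{ScanAgreement} objects
#' @return data.frame, one row per scan
#' @export
studyTable <- function(scans) {
  stopifnot(length(scans) > 0,
            all(vapply(scans, is, TRUE, "ScanAgreement")))
  out <- do.call(rbind, lapply(scans, as.data.frame))
  rownames(out) <- NULL
  out
}

#' Export a per-scan study table as TSV
#'
#' Areas with 1 decimal, dimensionless indices with 3 decimals.
#'
#' @param scans a study table (data.frame) or list of
#'   \linkS4class{ScanAgreement}
#' @param path output path
#' @export
writeStudyTable <- function(scans, path) {
  tab <- if (is.data.frame(scans)) scans else studyTable(scans)
  out <- tab
  for (col in intersect(c("MTA", "DE", "OE"), names(out)))
    out[[col]] <- sprintf("%.1f", out[[col]])
  for (col in intersect(c("OER", "SI", "JI"), names(out)))
    out[[col]] <- sprintf("%.3f", out[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Predicted Similarity Index at a given lesion burden
#'
#' The detection/outline decomposition of the Dice index gives
#' SI = 1 - OER/2 - DE/(2 MTA). Treating the mean Detection Error and
#' mean Outline Error Rate of a rater pair as burden-independent
#' constants, this predicts SI for any lesion burden (MTA). The value can
#' be negative at very small MTA; it is returned as-is (the model is
#' honest about its domain) and only plotting clamps it.
#'
#' @param meanDE mean Detection Error, mm^2
#' @param meanOER mean Outline Error Rate
#' @param mta Mean Total Area, mm^2 (vectorized; all > 0)
#' @return predicted SI
#' @examples
#' siEstimate(746.8, 0.4077, 5028)
#' @export
siEstimate <- function(meanDE, meanOER, mta) {
  if (any(!is.finite(mta)) || any(mta <= 0))
    stopDoee("mta must be positive and finite", "doeeDomainError")
  1 - meanOER / 2 - meanDE / (2 * mta)
}

#' Similarity Index / Jaccard Index conversions
#'
#' SI = 2 JI / (1 + JI) and JI = SI / (2 - SI); mutually inverse
#' bijections on [0, 1].
#'
#' @param ji,si values in [0, 1] (vectorized)
#' @return converted value(s)
#' @export
siFromJI <- function(ji) {
  if (any(ji < 0 | ji > 1 | !is.finite(ji)))
    stopDoee("ji must lie in [0, 1]", "doeeDomainError")
  2 * ji / (1 + ji)
}

#' @rdname siFromJI
#' @export
jiFromSI <- function(si) {
  if (any(si < 0 | si > 1 | !is.finite(si)))
    stopDoee("si must lie in [0, 1]", "doeeDomainError")
  si / (2 - si)
}

#' Cohen's kappa over a finite background frame
#'
#' Chance-corrected agreement for the per-pixel lesion/non-lesion
#' classification over a frame containing the union of both masks plus
#' \code{backgroundPixels} pixels marked by neither rater. Pixel counts
#' are taken at the mask (analysis) resolution, so frame sizes are
#' comparable across calls on the same pair. As the background grows,
#' kappa converges to the Similarity Index.
#'
#' @param pair a \linkS4class{RaterMaskPair}
#' @param backgroundPixels number of lesion-free pixels in the frame; must
#'   be at least the pixel count of the union
#' @return kappa (scalar)
#' @export
kappaOnFrame <- function(pair, backgroundPixels) {
  stopifnot(is(pair, "RaterMaskPair"))
  a <- sum(pair@rater1 & pair@rater2)
  b <- sum(pair@rater1 & !pair@rater2)
  c <- sum(!pair@rater1 & pair@rater2)
  unionPx <- a + b + c
  if (backgroundPixels < unionPx)
    stopDoee("frame smaller than the union of the two masks",
             "doeeDomainError")
  d <- backgroundPixels
  n <- a + b + c + d
  po <- (a + d) / n
  pe <- ((a + b) * (a + c) + (c + d) * (b + d)) / n^2
  (po - pe) / (1 - pe)
}
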