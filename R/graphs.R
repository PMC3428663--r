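#' Cumulative Detection Error curve
#'
#' For every area threshold t, counts the single-rater (CR1/CR2) regions
#' with area strictly greater than t — i.e. how many regions one rater
#' marked and the other missed, among regions larger than t. The curve is
#' a right-continuous, non-increasing step function; per-rater curves sum
#' to the total at every threshold. With \code{normalized = TRUE} counts
#' are divided by \code{nScans} to give a per-scan average.
#'
#' @param regions a region table (may span several scans)
#' @param normalized divide counts by \code{nScans}?
#' @param nScans number of scans represented (required when normalizing)
#' @return a \linkS4class{CumulativeCurve}
#' @export
cumulativeDetectionCurve <- function(regions, normalized = FALSE,
                                     nScans = 1L) {
  checkRegionTable(regions)
  if (normalized && nScans <= 0L)
    stopDoee("normalization requested with nScans = 0", "doeeDomainError")
  single <- regions[regions$label %in% c("CR1", "CR2"), , drop = FALSE]
  areas <- single$area_union
  rater <- as.integer(ifelse(single$label == "CR1", 1L, 2L))
  thresholds <- sort(unique(c(0, areas)))
  countAbove <- function(a, t) vapply(t, function(ti) sum(a > ti), 0)
  div <- if (normalized) as.integer(nScans) else 1L
  new("CumulativeCurve", areas = areas, rater = rater,
      thresholds = thresholds,
      total = countAbove(areas, thresholds) / div,
      r1Only = countAbove(areas[rater == 1L], thresholds) / div,
      r2Only = countAbove(areas[rater == 2L], thresholds) / div,
      normalized = isTRUE(normalized), nScans = as.integer(nScans))
}

#' Evaluate a Cumulative Detection Error curve at arbitrary thresholds
#'
#' @param curve a \linkS4class{CumulativeCurve}
#' @param threshold numeric vector of area thresholds (mm^2)
#' @param rater "both" (default), 1, or 2
#' @return counts of single-rater regions with area > threshold
#'   (per-scan average if the curve is normalized)
#' @export
countAbove <- function(curve, threshold, rater = "both") {
  stopifnot(is(curve, "CumulativeCurve"))
  a <- if (identical(rater, "both")) curve@areas
       else curve@areas[curve@rater == as.integer(rater)]
  div <- if (curve@normalized) curve@nScans else 1L
  vapply(threshold, function(t) sum(a > t), 0) / div
}

#' @export
setMethod("show", "CumulativeCurve", function(object) {
  cat(sprintf(
    "CumulativeCurve: %d single-rater regions (%d rater-1, %d rater-2)%s\n",
    length(object@areas), sum(object@rater == 1L), sum(object@rater == 2L),
    if (object@normalized) sprintf(", per-scan over %d scans", object@nScans)
    else ""))
})

#' Outline Error Distribution
#'
#' Histogram, over regions detected by both raters, of the signed relative
#' outline difference (|R2| - |R1|) / |R1 u R2|, which always lies in
#' [-1, 1]. Zero means identical outlines; negative values mean rater 1
#' drew the larger outline. Single-rater regions are excluded. An ideal
#' pair of raters gives a thin peak at 0. Bins are half-open [lo, hi)
#' over [-1, 1] with the last bin closed at 1.
#'
#' @param regions a region table
#' @param binWidth bin width; must divide 2 into an even number of bins
#'   so the bin set is symmetric about 0 (default 0.1)
#' @return an \linkS4class{OutlineHistogram}
#' @export
outlineErrorDistribution <- function(regions, binWidth = 0.1) {
  checkRegionTable(regions)
  nb <- 2 / binWidth
  if (abs(nb - round(nb)) > 1e-9 || round(nb) %% 2 != 0)
    stopDoee("binWidth must divide 2 into an even number of bins",
             "doeeDomainError")
  nb <- as.integer(round(nb))
  shared <- regions[regions$label == "CR12", , drop = FALSE]
  if (!nrow(shared))
    warning("no CR12 regions: empty outline histogram", call. = FALSE)
  stat <- (shared$area_r2 - shared$area_r1) / shared$area_union
  breaks <- seq(-1, 1, length.out = nb + 1L)
  bin <- pmin(floor((stat + 1) / binWidth) + 1L, nb)  # last bin closed
  new("OutlineHistogram", breaks = breaks,
      counts = tabulate(bin, nb), values = stat, binWidth = binWidth)
}

#' @export
setMethod("show", "OutlineHistogram", function(object) {
  cat(sprintf(
    "OutlineHistogram: %d shared regions, %d bins of width %.3g\n",
    length(object@values), length(object@counts), object@binWidth))
  if (length(object@values))
    cat(sprintf("  statistic: median %.3f, IQR [%.3f, %.3f]\n",
                stats::median(object@values),
                stats::quantile(object@values, 0.25),
                stats::quantile(object@values, 0.75)))
})

#' @export
setMethod("plot", signature(x = "CumulativeCurve", y = "missing"),
  function(x, ...) {
    ylab <- if (x@normalized) "detection errors per scan > threshold"
            else "detection errors > threshold"
    plot(x@thresholds, x@total, type = "s", lwd = 2, xlab =
           expression(paste("area threshold (", mm^2, ")")),
         ylab = ylab, main = "Cumulative Detection Error", ...)
    graphics::lines(x@thresholds, x@r1Only, type = "s", col = "blue")
    graphics::lines(x@thresholds, x@r2Only, type = "s", col = "red")
    graphics::legend("topright", c("total", "rater 1 only", "rater 2 only"),
                     col = c("black", "blue", "red"), lwd = c(2, 1, 1),
                     bty = "n")
    invisible(x)
  })

#' @export
setMethod("plot", signature(x = "OutlineHistogram", y = "missing"),
  function(x, ...) {
    if (!length(x@values)) {
      plot(0, 0, type = "n", xlim = c(-1, 1), ylim = c(0, 1), xlab = "",
           ylab = "", main = "Outline Error Distribution")
      graphics::text(0, 0.5, "no matched regions")
      return(invisible(x))
    }
    mids <- (x@breaks[-1] + x@breaks[-length(x@breaks)]) / 2
    graphics::barplot(x@counts, width = x@binWidth, space = 0,
                      names.arg = sprintf("%.1f", mids),
                      xlab = "(|R2| - |R1|) / |R1 u R2|   (< 0: rater 1 larger)",
                      ylab = "regions", main = "Outline Error Distribution",
                      ...)
    invisible(x)
  })

#' Render a diagnostic structure to an image file
#'
#' Writes a \linkS4class{CumulativeCurve} or \linkS4class{OutlineHistogram}
#' plot as PNG, SVG or PDF, chosen by the file extension.
#'
#' @param x the structure to render
#' @param path output file (.png, .svg or .pdf)
#' @param width,height device size in inches
#' @export
renderGraphs <- function(x, path, width = 6, height = 4.5) {
  ext <- tolower(tools::file_ext(path))
  dev <- switch(ext,
    png = function() grDevices::png(path, width = width, height = height,
                                    units = "in", res = 150),
    svg = function() grDevices::svg(path, width = width, height = height),
    pdf = function() grDevices::pdf(path, width = width, height = height),
    stop("unsupported image format: ", ext, call. = FALSE))
  dev()
  on.exit(grDevices::dev.off())
  plot(x)
  invisible(path)
}

#' Export curve points or histogram bins as TSV
#'
#' @param x a \linkS4class{CumulativeCurve} or
#'   \linkS4class{OutlineHistogram}
#' @param path output path
#' @export
writeGraphTable <- function(x, path) {
  tab <- if (is(x, "CumulativeCurve"))
    data.frame(threshold = x@thresholds, total = x@total,
               r1_only = x@r1Only, r2_only = x@r2Only)
  else if (is(x, "OutlineHistogram"))
    data.frame(bin_lo = x@breaks[-length(x@breaks)], bin_hi = x@breaks[-1],
               count = x@counts)
  else stop("unsupported object", call. = FALSE)
  utils::write.table(format(tab, digits = 10, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
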