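#' Construct a contour set
#'
#' @param slices list of slice records, each \code{list(index = <0-based
#'   slice index>, polygons = <list of n x 2 vertex matrices>)}. Vertex
#'   coordinates are 0-based pixel coordinates (x = column, y = row) under
#'   the vertex-on-pixel-center convention: integer coordinate (c, r) is
#'   the center of the pixel in column c, row r.
#' @param geometry a \linkS4class{PixelGeometry}
#' @return a \linkS4class{ContourSet}
#' @export
contourSet <- function(slices = list(), geometry = pixelGeometry(1, 1)) {
  slices <- lapply(slices, function(sl) {
    sl$index <- as.integer(sl$index)
    sl$polygons <- lapply(sl$polygons, function(p) {
      p <- as.matrix(p)
      storage.mode(p) <- "double"
      p
    })
    sl
  })
  new("ContourSet", slices = slices, geometry = geometry)
}

#' @export
setMethod("show", "ContourSet", function(object) {
  np <- sum(vapply(object@slices, function(s) length(s$polygons), 1L))
  cat(sprintf("ContourSet: %d slice(s), %d polygon(s), pixel %.4g x %.4g mm\n",
              length(object@slices), np, object@geometry@dx,
              object@geometry@dy))
})

# Vectorized even-odd (crossing-number) point-in-polygon test with the
# standard half-open boundary convention of scanline rasterizers: a point
# exactly on an edge is inside iff the polygon interior lies on its +x
# side. This keeps rasterized area unbiased (abutting polygons tile
# without overlap or gap) and makes area converge to the shoelace value.
pointsInPolygon <- function(px, py, vx, vy) {
  inside <- logical(length(px))
  n <- length(vx)
  j <- n
  for (i in seq_len(n)) {
    yi <- vy[i]; yj <- vy[j]
    if (yi != yj) {
      xi <- vx[i]; xj <- vx[j]
      cross <- (yi > py) != (yj > py)
      xint <- xi + (py - yi) * (xj - xi) / (yj - yi)
      # 1e-9 (pixel units) tie-break: keeps floating-point jitter on
      # samples that fall exactly on an edge from flipping the half-open
      # boundary rule
      inside <- xor(inside, cross & (px < xint - 1e-9))
    }
    j <- i
  }
  inside
}

# O(n^2) self-intersection scan; polygons drawn by hand are small.
polygonSelfIntersects <- function(p) {
  n <- nrow(p)
  if (n < 4L) return(FALSE)
  seg <- cbind(p, p[c(2:n, 1L), , drop = FALSE])
  ccw <- function(ax, ay, bx, by, cx, cy)
    (by - ay) * (cx - ax) - (bx - ax) * (cy - ay)
  for (i in 1:(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      d1 <- ccw(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 1], seg[j, 2])
      d2 <- ccw(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 3], seg[j, 4])
      d3 <- ccw(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 1], seg[i, 2])
      d4 <- ccw(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 3], seg[i, 4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
        return(TRUE)
    }
  }
  FALSE
}

#' Rasterize polygon contours to an upsampled binary mask stack
#'
#' Converts closed-path outlines to a binary mask by sampling the grid at
#' \code{factor} times the image resolution in x and y (default 5, which
#' keeps a single closed path from splitting into several regions when it
#' has a sub-pixel narrow neck). A fine pixel is set when its center falls
#' inside any polygon of the slice (even-odd rule, half-open boundary
#' convention). The effective pixel area is scaled by 1/factor^2 so
#' physical areas are preserved.
#'
#' @param contours a \linkS4class{ContourSet}
#' @param gridShape integer (rows, cols) of the native image grid
#' @param factor integer upsampling factor (>= 1)
#' @param nSlices number of slices in the output stack; default covers
#'   0..max slice index present (one empty slice if none)
#' @return list with \code{mask} (logical array, (factor*rows) x
#'   (factor*cols) x nSlices), \code{geometry} (the effective fine-pixel
#'   \linkS4class{PixelGeometry}) and \code{factor}
#' @export
rasterizeContours <- function(contours, gridShape, factor = 5L,
                              nSlices = NULL) {
  stopifnot(is(contours, "ContourSet"), length(gridShape) == 2L,
            factor >= 1L)
  factor <- as.integer(factor)
  rows <- as.integer(gridShape[1]); cols <- as.integer(gridShape[2])
  idx <- vapply(contours@slices, function(s) s$index, 1L)
  if (is.null(nSlices))
    nSlices <- if (length(idx)) max(idx) + 1L else 1L
  if (length(idx) && max(idx) + 1L > nSlices)
    stop("slice index ", max(idx), " exceeds nSlices = ", nSlices,
         call. = FALSE)
  fr <- factor * rows; fc <- factor * cols
  mask <- array(FALSE, c(fr, fc, nSlices))
  # fine-pixel centers in native pixel coordinates
  xs <- (seq_len(fc) - 0.5) / factor - 0.5
  ys <- (seq_len(fr) - 0.5) / factor - 0.5
  for (sl in contours@slices) {
    plane <- sl$index + 1L
    for (p in sl$polygons) {
      if (nrow(p) < 3L)
        stopDoee("polygon has fewer than 3 vertices", "doeeValidationError")
      if (any(p[, 1] < -0.5 | p[, 1] > cols - 0.5 |
              p[, 2] < -0.5 | p[, 2] > rows - 0.5))
        stopDoee("polygon vertex outside grid bounds", "doeeValidationError")
      if (polygonSelfIntersects(p))
        warning("self-intersecting polygon resolved by the even-odd rule",
                call. = FALSE)
      ci <- which(xs >= min(p[, 1]) - 1e-9 & xs <= max(p[, 1]) + 1e-9)
      ri <- which(ys >= min(p[, 2]) - 1e-9 & ys <= max(p[, 2]) + 1e-9)
      if (!length(ci) || !length(ri)) next
      px <- rep(xs[ci], each = length(ri))
      py <- rep(ys[ri], times = length(ci))
      inside <- pointsInPolygon(px, py, p[, 1], p[, 2])
      sub <- mask[ri, ci, plane]
      mask[ri, ci, plane] <- sub | matrix(inside, length(ri), length(ci))
    }
  }
  list(mask = mask,
       geometry = pixelGeometry(contours@geometry@dx / factor,
                                contours@geometry@dy / factor),
       factor = factor)
}

#' Shoelace area of a closed polygon
#'
#' Exact signed-area magnitude of a simple polygon, in the units of its
#' vertex coordinates squared; used as the analytic reference for
#' rasterization accuracy.
#'
#' @param p n x 2 vertex matrix
#' @return area (>= 0)
#' @export
polygonArea <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  n <- nrow(p)
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Read a single-rater binary mask volume
#'
#' Reads a NIfTI volume (.nii / .nii.gz) or a stack of 2-D grayscale PNG
#' images (a character vector of paths, one per slice) and thresholds
#' values strictly above zero. Pixel geometry is taken from the NIfTI
#' header when present; an explicit \code{geometry} argument wins on
#' conflict with a warning. PNG files carry no geometry, so the argument
#' is required for them.
#'
#' @param path file path (NIfTI) or character vector of PNG paths
#' @param geometry optional \linkS4class{PixelGeometry} override
#' @return list with \code{mask} (logical rows x cols x slices array) and
#'   \code{geometry}
#' @export
readMaskVolume <- function(path, geometry = NULL) {
  if (length(path) > 1L || grepl("\\.png$", path[1], ignore.case = TRUE)) {
    planes <- lapply(path, function(f) {
      img <- png::readPNG(f)
      if (length(dim(img)) == 3L) img <- img[, , 1]
      img > 0
    })
    d <- dim(planes[[1]])
    if (!all(vapply(planes, function(m) identical(dim(m), d), TRUE)))
      stopDoee("PNG slices have inconsistent dimensions", "doeePairingError")
    mask <- array(unlist(planes), c(d, length(planes)))
    if (is.null(geometry))
      stop("PNG masks carry no pixel geometry; supply 'geometry'",
           call. = FALSE)
    return(list(mask = mask, geometry = geometry))
  }
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) > 3L)
    stop("expected a 2-D or 3-D mask volume", call. = FALSE)
  headerGeom <- if (length(pd) >= 2L && all(is.finite(pd[1:2])) &&
                    all(pd[1:2] > 0)) pixelGeometry(pd[1], pd[2]) else NULL
  if (!is.null(geometry)) {
    if (!is.null(headerGeom) &&
        (abs(headerGeom@dx - geometry@dx) > 1e-6 ||
         abs(headerGeom@dy - geometry@dy) > 1e-6))
      warning(sprintf(
        "header geometry (%.4g x %.4g mm) overridden by argument (%.4g x %.4g mm)",
        headerGeom@dx, headerGeom@dy, geometry@dx, geometry@dy),
        call. = FALSE)
  } else {
    geometry <- headerGeom
    if (is.null(geometry))
      stop("no pixel geometry in header; supply 'geometry'", call. = FALSE)
  }
  list(mask = array(arr > 0, dim(arr)), geometry = geometry)
}

#' Pair two rater mask stacks for one scan
#'
#' @param rater1,rater2 logical/0-1 matrices or 3-d arrays, or results of
#'   \code{\link{readMaskVolume}} / \code{\link{rasterizeContours}}
#' @param geometry a \linkS4class{PixelGeometry}; defaults to the geometry
#'   carried by the inputs, else 1 x 1 mm pixels
#' @param scanId opaque scan label
#' @return a \linkS4class{RaterMaskPair}
#' @export
raterMaskPair <- function(rater1, rater2, geometry = NULL, scanId = "scan") {
  pull <- function(x) {
    if (is.list(x) && !is.null(x$mask)) list(m = x$mask, g = x$geometry)
    else list(m = x, g = NULL)
  }
  a <- pull(rater1); b <- pull(rater2)
  m1 <- asMaskStack(a$m, "rater1 mask")
  m2 <- asMaskStack(b$m, "rater2 mask")
  if (!identical(dim(m1), dim(m2)))
    stopDoee(sprintf("rater mask shapes differ: %s vs %s",
                     paste(dim(m1), collapse = "x"),
                     paste(dim(m2), collapse = "x")), "doeePairingError")
  if (is.null(geometry)) geometry <- a$g
  if (is.null(geometry)) geometry <- b$g
  if (is.null(geometry)) geometry <- pixelGeometry(1, 1)
  new("RaterMaskPair", rater1 = m1, rater2 = m2, geometry = geometry,
      scanId = as.character(scanId))
}

#' @export
setMethod("show", "RaterMaskPair", function(object) {
  d <- dim(object@rater1)
  pa <- pixelArea(object@geometry)
  cat(sprintf(
    "RaterMaskPair '%s': %d x %d x %d, |R1| = %.1f mm^2, |R2| = %.1f mm^2\n",
    object@scanId, d[1], d[2], d[3], sum(object@rater1) * pa,
    sum(object@rater2) * pa))
})

jsonSchemaStop <- function(field)
  stopDoee(sprintf("contour JSON: missing or invalid field '%s'", field),
           "doeeSchemaError")

#' Write / read the contour JSON dialect
#'
#' Serializes a \linkS4class{ContourSet} as
#' \code{{"geometry": {"dx":, "dy":}, "slices": [{"index":, "polygons":
#' [[[x, y], ...], ...]}]}} with 0-based pixel coordinates (x = column,
#' y = row, vertex-on-pixel-center). Coordinates round-trip losslessly.
#'
#' @param contours a \linkS4class{ContourSet}
#' @param path output / input file path
#' @return \code{readContoursJSON} returns a \linkS4class{ContourSet};
#'   \code{writeContoursJSON} returns \code{path} invisibly.
#' @export
writeContoursJSON <- function(contours, path) {
  stopifnot(is(contours, "ContourSet"))
  obj <- list(
    geometry = list(dx = contours@geometry@dx, dy = contours@geometry@dy),
    slices = lapply(contours@slices, function(sl) list(
      index = sl$index,
      polygons = lapply(sl$polygons, function(p)
        lapply(seq_len(nrow(p)), function(i) c(p[i, 1], p[i, 2])))
    ))
  )
  # I(17) = 17 significant digits: enough to round-trip any double
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17),
                           always_decimal = FALSE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname writeContoursJSON
#' @export
readContoursJSON <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stopDoee(paste("malformed contour JSON:",
                                   conditionMessage(e)), "doeeSchemaError"))
  g <- obj$geometry
  if (is.null(g) || is.null(g$dx) || is.null(g$dy) ||
      !is.numeric(g$dx) || !is.numeric(g$dy))
    jsonSchemaStop("geometry")
  if (is.null(obj$slices) || !is.list(obj$slices))
    jsonSchemaStop("slices")
  slices <- lapply(obj$slices, function(sl) {
    if (is.null(sl$index) || !is.numeric(sl$index) || sl$index < 0)
      jsonSchemaStop("slices[].index")
    if (is.null(sl$polygons) || !is.list(sl$polygons))
      jsonSchemaStop("slices[].polygons")
    polys <- lapply(sl$polygons, function(pp) {
      if (length(pp) < 3L)
        jsonSchemaStop("slices[].polygons (fewer than 3 vertices)")
      ok <- all(vapply(pp, function(v)
        is.list(v) || is.numeric(v), TRUE))
      verts <- lapply(pp, function(v) {
        v <- unlist(v)
        if (length(v) != 2L || !is.numeric(v))
          jsonSchemaStop("slices[].polygons[][] (vertex must be [x, y])")
        v
      })
      do.call(rbind, verts)
    })
    list(index = as.integer(sl$index), polygons = polys)
  })
  contourSet(slices, pixelGeometry(g$dx, g$dy))
}
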