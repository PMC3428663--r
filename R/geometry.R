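#' Construct a pixel geometry
#'
#' @param dx pixel width in mm
#' @param dy pixel height in mm (defaults to \code{dx})
#' @return a \linkS4class{PixelGeometry}
#' @examples
#' pixelGeometry(0.94)
#' @export
pixelGeometry <- function(dx, dy = dx) {
  new("PixelGeometry", dx = as.numeric(dx), dy = as.numeric(dy))
}

#' @describeIn pixelGeometry area of one pixel in mm^2
#' @param geometry a \linkS4class{PixelGeometry}
#' @export
pixelArea <- function(geometry) geometry@dx * geometry@dy

#' @export
setMethod("show", "PixelGeometry", function(object) {
  cat(sprintf("PixelGeometry: %.4g x %.4g mm (%.4g mm^2/pixel)\n",
              object@dx, object@dy, pixelArea(object)))
})
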