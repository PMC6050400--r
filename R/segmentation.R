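#' Construct a PlotImage
#'
#' @param pixels `H x W x 3` numeric array of 8-bit channel values
#'   (`[0, 255]`); coerced to integer.
#' @param plotId plot identifier.
#' @param mmPerPx ground resolution in mm per pixel (default 0.9, the
#'   nominal resolution of the overhead plot camera).
#' @return A [PlotImage-class] object.
#' @examples
#' px <- array(0L, c(4, 8, 3)); px[, , 2] <- 200L
#' PlotImage(px, "demo")
#' @export
PlotImage <- function(pixels, plotId = "plot", mmPerPx = 0.9) {
  storage.mode(pixels) <- "integer"
  new("PlotImage", pixels = pixels, plotId = as.character(plotId),
      mmPerPx = mmPerPx)
}

#' Compute the per-pixel hue map of a plot image
#'
#' Converts the RGB raster to HSV and returns the hue channel in degrees
#' on `[0, 360)`. Hue is undefined where chroma is zero (gray pixels,
#' including pure black and white); those pixels are marked undefined and
#' never enter a plant mask. Saturation and value are computed as part of
#' the conversion but only hue (and its definedness) is retained, since
#' segmentation is hue-only.
#'
#' @param image a [PlotImage-class].
#' @return A [HueMap-class] on the same grid.
#' @examples
#' px <- array(0L, c(2, 5, 3)); px[, , 2] <- 255L
#' computeHue(PlotImage(px))  # pure green, hue 120 everywhere
#' @export
computeHue <- function(image) {
  stopifnot(is(image, "PlotImage"))
  px <- image@pixels
  d <- dim(px)
  rgb <- rbind(as.vector(px[, , 1]), as.vector(px[, , 2]),
               as.vector(px[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 255)
  # snap to nanodegrees: hues of 8-bit pixels are rationals spaced well
  # above 1e-9 apart, and this keeps exact boundary hues (e.g. 40) on
  # the inclusive side of the segmentation window
  hue <- matrix(round(hsv[1, ] * 360 * 1e9) / 1e9, d[1], d[2])
  mx <- pmax(rgb[1, ], rgb[2, ], rgb[3, ])
  mn <- pmin(rgb[1, ], rgb[2, ], rgb[3, ])
  defined <- matrix(mx > mn, d[1], d[2])
  hue[!defined] <- NA_real_
  hue[defined & hue >= 360] <- 0  # guard the circle boundary
  new("HueMap", hue = hue, defined = defined)
}

#' Segment plant pixels by a hue window
#'
#' Initial plant segmentation: a pixel is plant when its hue is defined
#' and falls in the closed window `[loDeg, hiDeg]` (default 40-170
#' degrees, covering the orange-yellow-green range of healthy and
#' chlorotic soybean canopy while excluding soil, whose hue lies below
#' 40 degrees).
#'
#' @param hueMap a [HueMap-class].
#' @param loDeg,hiDeg window endpoints in degrees, `0 <= loDeg < hiDeg < 360`.
#' @return A [PlantMask-class] with provenance `"raw_segmentation"`.
#' @export
segmentByHue <- function(hueMap, loDeg = 40, hiDeg = 170) {
  stopifnot(is(hueMap, "HueMap"))
  if (!(loDeg < hiDeg) || loDeg < 0 || hiDeg >= 360)
    stop("require 0 <= loDeg < hiDeg < 360")
  m <- hueMap@defined & !is.na(hueMap@hue) &
    hueMap@hue >= loDeg & hueMap@hue <= hiDeg
  m[is.na(m)] <- FALSE
  new("PlantMask", mask = m, provenance = "raw_segmentation")
}

#' Remove isolated noise by morphological opening
#'
#' Binary opening (erosion then dilation) with a disk structuring element,
#' removing speckle smaller than the disk while leaving large canopy
#' blobs intact. Pixels outside the image are treated as foreground
#' during erosion and background during dilation, so a canopy reaching
#' the image border is not eaten away.
#'
#' @param plantMask a [PlantMask-class] with provenance
#'   `"raw_segmentation"`.
#' @param radiusPx disk radius in pixels (default 2, about 1.8 mm at the
#'   nominal 0.9 mm/px resolution: larger than sensor speckle, smaller
#'   than a leaflet).
#' @return A [PlantMask-class] with provenance `"opened"`; always a
#'   subset of the input mask.
#' @export
morphologicalOpen <- function(plantMask, radiusPx = 2L) {
  stopifnot(is(plantMask, "PlantMask"))
  if (plantMask@provenance != "raw_segmentation")
    stop("morphologicalOpen expects a raw_segmentation mask")
  if (radiusPx < 1L) stop("radiusPx must be >= 1")
  kern <- diskKernel(radiusPx)
  opened <- EBImage::opening(plantMask@mask * 1, kern) > 0.5
  new("PlantMask", mask = opened & plantMask@mask, provenance = "opened")
}
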