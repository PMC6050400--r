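#' Assign hues to the five colour classes
#'
#' The segmentation window `[40, 170]` degrees is partitioned into five
#' contiguous half-open classes: Orange-Yellow `[40, 51)`, Yellow
#' `[51, 61)`, Yellow-Green `[61, 81)`, Green `[81, 141)` and Green-Cyan
#' `[141, 170]`. Hues outside the window map to `"outside"`. The
#' partition is contiguous and gap-free so that the five class fractions
#' of any segmented plot sum exactly to 1.
#'
#' @param hueDeg numeric vector of hues in degrees on `[0, 360)`; `NA`
#'   (undefined hue) maps to `"outside"`.
#' @param edges numeric vector of 6 increasing class boundaries
#'   (default `c(40, 51, 61, 81, 141, 170)`).
#' @return Factor with levels `OY`, `Y`, `YG`, `G`, `GC`, `outside`.
#' @examples
#' binHue(c(45, 55, 70, 120, 150, 20))
#' @export
binHue <- function(hueDeg, edges = c(40, 51, 61, 81, 141, 170)) {
  if (length(edges) != 6L || is.unsorted(edges, strictly = TRUE))
    stop("edges must be 6 strictly increasing boundaries")
  lv <- c("OY", "Y", "YG", "G", "GC", "outside")
  idx <- findInterval(hueDeg, edges)            # 0..6; right edge -> 6
  idx[is.na(idx) | idx == 0L | idx == 6L] <- 6L # below window or > hi
  idx[hueDeg == edges[6]] <- 5L                 # hi endpoint is in GC
  factor(lv[idx], levels = lv)
}

#' Extract the six colour features of a plot
#'
#' From the weed-excluded plant mask and the hue map: the Plant Pixel
#' Count (PPC), its fraction of all image pixels (PPCF), and the fraction
#' of plant pixels in each of the five hue classes. For an empty mask all
#' quantities are 0; otherwise the five fractions sum exactly to 1
#' because the class partition covers the segmentation window.
#'
#' @param hueMap a [HueMap-class].
#' @param plantMask a [PlantMask-class] with provenance
#'   `"weed_excluded"`.
#' @param plotId plot identifier carried into the result.
#' @param edges class boundaries passed to [binHue()].
#' @return A [ColorFeatures-class] object.
#' @export
extractFeatures <- function(hueMap, plantMask, plotId = "plot",
                            edges = c(40, 51, 61, 81, 141, 170)) {
  stopifnot(is(hueMap, "HueMap"), is(plantMask, "PlantMask"))
  if (!identical(dim(hueMap@hue), dim(plantMask@mask)))
    stop("hue map and mask must share dimensions")
  if (plantMask@provenance != "weed_excluded")
    stop("extractFeatures expects a weed_excluded mask")
  ppc <- sum(plantMask@mask)
  total <- length(plantMask@mask)
  nm <- c("ratio_oy", "ratio_y", "ratio_yg", "ratio_g", "ratio_gc")
  if (ppc == 0L) {
    ratios <- stats::setNames(numeric(5), nm)
  } else {
    cls <- binHue(hueMap@hue[plantMask@mask], edges)
    counts <- table(cls)[c("OY", "Y", "YG", "G", "GC")]
    if (sum(counts) != ppc)
      stop("masked pixels fall outside the colour classes; ",
           "mask and bin edges are inconsistent")
    ratios <- stats::setNames(as.numeric(counts) / ppc, nm)
  }
  new("ColorFeatures", plotId = as.character(plotId), ppc = as.integer(ppc),
      ppcf = ppc / total, ratios = ratios)
}

#' Flatten ColorFeatures to a one-row data.frame
#'
#' @param x a [ColorFeatures-class].
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return data.frame with columns `plot_id`, `ppc`, `ppcf`, `ratio_gc`,
#'   `ratio_g`, `ratio_yg`, `ratio_y`, `ratio_oy`.
#' @export
as.data.frame.ColorFeatures <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  r <- as.list(x@ratios)
  data.frame(plot_id = x@plotId, ppc = x@ppc, ppcf = x@ppcf,
             ratio_gc = r$ratio_gc, ratio_g = r$ratio_g,
             ratio_yg = r$ratio_yg, ratio_y = r$ratio_y,
             ratio_oy = r$ratio_oy)
}

setMethod("as.data.frame", "ColorFeatures", as.data.frame.ColorFeatures)
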