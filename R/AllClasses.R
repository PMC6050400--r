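#' @import methods
NULL

#' Overhead RGB image of one two-row field plot
#'
#' Container for an 8-bit RGB raster of a single plot together with the
#' plot identifier and the ground resolution. Pixels are stored as an
#' `H x W x 3` integer array in row-major image orientation (row index
#' increases downwards); channel values lie in `[0, 255]`.
#'
#' @slot pixels integer array, `H x W x 3`, values in `[0, 255]`.
#' @slot plotId character scalar, opaque plot identifier.
#' @slot mmPerPx positive numeric scalar, ground resolution in mm per pixel.
#'
#' @seealso [PlotImage()], [readPlotImage()], [computeHue()]
#' @export
setClass("PlotImage",
  representation(pixels = "array", plotId = "character", mmPerPx = "numeric"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (length(d) != 3L || d[3] != 3L)
      return("pixels must be an H x W x 3 array")
    if (d[1] < 2L || d[2] < 5L)
      return("image must be at least 2 rows tall and 5 columns wide")
    if (anyNA(object@pixels) ||
        min(object@pixels) < 0 || max(object@pixels) > 255)
      return("channel values must lie in [0, 255]")
    if (length(object@mmPerPx) != 1L || object@mmPerPx <= 0)
      return("mmPerPx must be a positive scalar")
    TRUE
  })

#' Per-pixel hue map in degrees
#'
#' Hue channel of the HSV decomposition of a [PlotImage], in degrees on the
#' `[0, 360)` circle. Hue is undefined where chroma is zero (gray pixels);
#' those pixels are flagged in `defined` and always treated as non-plant.
#'
#' @slot hue numeric matrix, hue in degrees; `NA` where undefined.
#' @slot defined logical matrix, `TRUE` where hue is defined.
#' @export
setClass("HueMap",
  representation(hue = "matrix", defined = "matrix"),
  validity = function(object) {
    if (!identical(dim(object@hue), dim(object@defined)))
      return("hue and defined must share dimensions")
    h <- object@hue[object@defined]
    if (length(h) && (anyNA(h) || min(h) < 0 || max(h) >= 360))
      return("defined hue values must lie in [0, 360)")
    TRUE
  })

#' Binary plant/background mask
#'
#' Boolean raster on the image grid marking plant pixels, carrying the
#' processing stage it came from. Masks form a subset chain:
#' `weed_excluded` \eqn{\subseteq} `opened` \eqn{\subseteq}
#' `raw_segmentation`.
#'
#' @slot mask logical matrix.
#' @slot provenance one of `"raw_segmentation"`, `"opened"`,
#'   `"weed_excluded"`.
#' @export
setClass("PlantMask",
  representation(mask = "matrix", provenance = "character"),
  validity = function(object) {
    if (!is.logical(object@mask))
      return("mask must be logical")
    if (!object@provenance %in%
        c("raw_segmentation", "opened", "weed_excluded"))
      return("unknown provenance")
    TRUE
  })

#' Detected crop-line positions
#'
#' Per half-image (top row, bottom row) and per vertical section, the
#' pixel row (`y`) at which the crop line was located. Coordinates are
#' 1-based full-image coordinates; sections partition the image width
#' left to right.
#'
#' @slot lines data.frame with columns `row` (1 = top half, 2 = bottom
#'   half), `section`, `x_start`, `x_end`, `y_line`.
#' @slot dim integer vector `c(H, W)` of the source image.
#' @export
setClass("CropLineMap",
  representation(lines = "data.frame", dim = "integer"),
  validity = function(object) {
    need <- c("row", "section", "x_start", "x_end", "y_line")
    if (!all(need %in% names(object@lines)))
      return("lines must have columns row, section, x_start, x_end, y_line")
    if (!all(object@lines$row %in% c(1L, 2L)))
      return("row must be 1 (top) or 2 (bottom)")
    TRUE
  })

#' Thin crop-line seed mask
#'
#' Boolean raster, true within `(thickness - 1) / 2` rows of a detected
#' crop line inside that section's column range. Used to seed retention
#' in [excludeWeeds()].
#'
#' @slot mask logical matrix.
#' @slot thicknessPx odd positive integer, line thickness in pixels.
#' @export
setClass("LineMask",
  representation(mask = "matrix", thicknessPx = "integer"),
  validity = function(object) {
    t <- object@thicknessPx
    if (length(t) != 1L || t < 1L || t %% 2L == 0L)
      return("thicknessPx must be an odd positive integer")
    TRUE
  })

#' Per-plot colour features
#'
#' The six parameters extracted from a weed-excluded plot mask: plant
#' pixel count (PPC), its fraction of the image (PPCF), and the fractions
#' of plant pixels in the Orange-Yellow, Yellow, Yellow-Green, Green and
#' Green-Cyan hue classes. The five class fractions sum to 1 whenever
#' `ppc > 0` and are all 0 for an empty mask.
#'
#' @slot plotId character scalar.
#' @slot ppc non-negative integer, plant pixel count.
#' @slot ppcf numeric in `[0, 1]`, `ppc / (H * W)`.
#' @slot ratios named numeric of length 5:
#'   `ratio_oy`, `ratio_y`, `ratio_yg`, `ratio_g`, `ratio_gc`.
#' @export
setClass("ColorFeatures",
  representation(plotId = "character", ppc = "integer", ppcf = "numeric",
                 ratios = "numeric"),
  validity = function(object) {
    if (!identical(names(object@ratios),
                   c("ratio_oy", "ratio_y", "ratio_yg", "ratio_g",
                     "ratio_gc")))
      return("ratios must be named ratio_oy, ratio_y, ratio_yg, ratio_g, ratio_gc")
    if (object@ppc < 0L) return("ppc must be non-negative")
    s <- sum(object@ratios)
    if (object@ppc > 0L && abs(s - 1) > 1e-9)
      return("class fractions must sum to 1 when ppc > 0")
    if (object@ppc == 0L && s != 0)
      return("class fractions must all be 0 when ppc = 0")
    TRUE
  })

#' Trained IDC computer-scoring model
#'
#' Fitted model mapping per-plot colour features to integer IDC scores in
#' `{1..9}`. `method` is `"LDA"` (Gaussian linear discriminant analysis
#' with shared covariance) or `"SVM"` (epsilon-insensitive support-vector
#' regression with RBF kernel, integerized at prediction time).
#'
#' @slot method `"LDA"` or `"SVM"`.
#' @slot featureNames character, feature columns used (and their order).
#' @slot fit fitted parameters: for LDA a list (class means, inverse pooled
#'   covariance, log priors, classes, ridge used); for SVM the `e1071::svm`
#'   object.
#' @slot center,scale numeric, feature standardization from training data
#'   (SVM; zero-length for LDA).
#' @slot cvTable data.frame of the CV grid (`cost`, `epsilon`, `rmse`) for
#'   SVM; empty for LDA.
#' @slot hyper named list of selected hyperparameters and the training seed.
#' @export
setClass("IdcScorer",
  representation(method = "character", featureNames = "character",
                 fit = "ANY", center = "numeric", scale = "numeric",
                 cvTable = "data.frame", hyper = "list"),
  validity = function(object) {
    if (!object@method %in% c("LDA", "SVM"))
      return("method must be LDA or SVM")
    TRUE
  })

#' 9 x 9 confusion matrix for IDC scores
#'
#' Counts of computer score (rows) against reference score (columns) on
#' the 1-9 IDC scale. Accuracy I is the exact-match rate; Accuracy II also
#' counts one-point-off predictions as correct.
#'
#' @slot counts 9 x 9 integer matrix, rows = computer score, columns =
#'   reference score.
#' @seealso [confusionMatrix9()], [accuracyI()], [accuracyII()]
#' @export
setClass("ConfusionMatrix9",
  representation(counts = "matrix"),
  validity = function(object) {
    if (!identical(dim(object@counts), c(9L, 9L)))
      return("counts must be 9 x 9")
    if (anyNA(object@counts) || any(object@counts < 0))
      return("counts must be non-negative")
    TRUE
  })

#' Synthetic scene specification
#'
#' Parameters of one synthetic two-row plot scene: image size, row
#' positions, per-row canopy cover, IDC severity (which sets the canopy
#' hue mixture over the five colour classes), weed and soil properties,
#' salt-noise rate, and the seed. Defaults emulate a scaled-down overhead
#' plot image; see the methods vignette for the calibration.
#'
#' @slot height,width image size in pixels.
#' @slot rowY numeric length 2, row centre lines (1-based pixel rows).
#' @slot cover numeric length 2 in `[0, 1]`, target fraction of columns
#'   covered by canopy at each row line.
#' @slot severity integer 1-9.
#' @slot mixture named numeric length 5, hue-class proportions
#'   (`oy`, `y`, `yg`, `g`, `gc`); derived from severity by default.
#' @slot blobRadius numeric length 2, min/max canopy blob radius (px).
#' @slot weedCount integer, number of off-row weed blobs.
#' @slot weedRadius numeric length 2, min/max weed radius (px).
#' @slot weedMargin numeric, minimum |y - rowY| distance of weed pixels
#'   from either row line (px); must exceed half the line-mask thickness.
#' @slot soilHue numeric length 2, soil hue range in degrees (outside the
#'   plant segmentation window).
#' @slot noiseRate numeric, fraction of pixels turned into isolated
#'   in-window salt noise.
#' @slot seed integer RNG seed.
#' @export
setClass("SceneSpec",
  representation(height = "integer", width = "integer", rowY = "numeric",
                 cover = "numeric", severity = "integer",
                 mixture = "numeric", blobRadius = "numeric",
                 weedCount = "integer", weedRadius = "numeric",
                 weedMargin = "numeric", soilHue = "numeric",
                 noiseRate = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@height < 2L || object@width < 5L)
      return("scene must be at least 2 x 5")
    if (!object@severity %in% 1:9) return("severity must be in 1..9")
    if (abs(sum(object@mixture) - 1) > 1e-8)
      return("mixture proportions must sum to 1")
    if (any(object@cover < 0 | object@cover > 1))
      return("cover must be in [0, 1]")
    TRUE
  })

#' Ground truth of a synthetic scene
#'
#' Pixel-exact truth for one generated scene: disjoint canopy, weed and
#' soil masks covering the image (isolated noise pixels are annotated
#' separately and counted as soil), the true row positions and severity,
#' and the hue-class proportions actually realized on the canopy.
#'
#' @slot canopy,weed,soil,noise logical matrices on the image grid.
#' @slot rowY numeric length 2.
#' @slot severity integer 1-9.
#' @slot realizedProportions named numeric length 5 (class proportions of
#'   the canopy pixels actually drawn).
#' @export
setClass("SceneTruth",
  representation(canopy = "matrix", weed = "matrix", soil = "matrix",
                 noise = "matrix", rowY = "numeric", severity = "integer",
                 realizedProportions = "numeric"),
  validity = function(object) {
    if (any(object@canopy & object@weed) || any(object@canopy & object@soil) ||
        any(object@weed & object@soil))
      return("canopy, weed, soil masks must be pairwise disjoint")
    if (!all(object@canopy | object@weed | object@soil))
      return("canopy, weed, soil masks must cover the image")
    TRUE
  })
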