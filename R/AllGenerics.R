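#' @rdname PlotImage-class
#' @param object a `PlotImage`
#' @export
setGeneric("plotId", function(object) standardGeneric("plotId"))

#' @rdname PlotImage-class
#' @export
setGeneric("mmPerPx", function(object) standardGeneric("mmPerPx"))

#' Extract the pixel raster / mask matrix of an object
#'
#' @param object a `PlotImage`, `PlantMask`, `LineMask` or `HueMap`.
#' @return For `PlotImage` the `H x W x 3` integer array; for masks the
#'   logical matrix; for `HueMap` the hue matrix in degrees.
#' @export
setGeneric("pixelData", function(object) standardGeneric("pixelData"))

#' @rdname HueMap-class
#' @param object a `HueMap`
#' @export
setGeneric("definedMask", function(object) standardGeneric("definedMask"))

#' @rdname PlantMask-class
#' @param object a `PlantMask`
#' @export
setGeneric("maskProvenance", function(object) standardGeneric("maskProvenance"))

#' @rdname CropLineMap-class
#' @param object a `CropLineMap`
#' @export
setGeneric("cropLines", function(object) standardGeneric("cropLines"))

setMethod("plotId", "PlotImage", function(object) object@plotId)
setMethod("mmPerPx", "PlotImage", function(object) object@mmPerPx)
setMethod("pixelData", "PlotImage", function(object) object@pixels)
setMethod("pixelData", "PlantMask", function(object) object@mask)
setMethod("pixelData", "LineMask", function(object) object@mask)
setMethod("pixelData", "HueMap", function(object) object@hue)
setMethod("definedMask", "HueMap", function(object) object@defined)
setMethod("maskProvenance", "PlantMask", function(object) object@provenance)
setMethod("cropLines", "CropLineMap", function(object) object@lines)

setMethod("show", "PlotImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("PlotImage '%s': %d x %d px, %.2f mm/px\n",
              object@plotId, d[1], d[2], object@mmPerPx))
})

setMethod("show", "HueMap", function(object) {
  cat(sprintf("HueMap: %d x %d px, %.1f%% defined\n",
              nrow(object@hue), ncol(object@hue),
              100 * mean(object@defined)))
})

setMethod("show", "PlantMask", function(object) {
  cat(sprintf("PlantMask (%s): %d x %d px, %d plant pixels (%.1f%%)\n",
              object@provenance, nrow(object@mask), ncol(object@mask),
              sum(object@mask), 100 * mean(object@mask)))
})

setMethod("show", "CropLineMap", function(object) {
  cat(sprintf("CropLineMap: %d sections per row on a %d x %d image\n",
              sum(object@lines$row == 1L), object@dim[1], object@dim[2]))
  print(object@lines, row.names = FALSE)
})

setMethod("show", "LineMask", function(object) {
  cat(sprintf("LineMask: %d x %d px, thickness %d px, %d seed pixels\n",
              nrow(object@mask), ncol(object@mask), object@thicknessPx,
              sum(object@mask)))
})

setMethod("show", "ColorFeatures", function(object) {
  cat(sprintf("ColorFeatures '%s': PPC = %d, PPCF = %.4f\n",
              object@plotId, object@ppc, object@ppcf))
  print(round(object@ratios, 4))
})

setMethod("show", "IdcScorer", function(object) {
  cat(sprintf("IdcScorer (%s) on features: %s\n", object@method,
              paste(object@featureNames, collapse = ", ")))
  if (object@method == "SVM" && nrow(object@cvTable))
    cat(sprintf("  selected cost = %g, epsilon = %g (CV RMSE %.4f)\n",
                object@hyper$cost, object@hyper$epsilon,
                min(object@cvTable$rmse)))
})

setMethod("show", "ConfusionMatrix9", function(object) {
  cat("ConfusionMatrix9 (rows = computer score, cols = reference score)\n")
  print(object@counts)
  cat(sprintf("Accuracy I = %.1f%%\nAccuracy II = %.1f%%\n",
              accuracyI(object), accuracyII(object)))
})

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf(
    "SceneSpec: %d x %d px, rows at y = %s, severity %d, seed %d\n",
    object@height, object@width,
    paste(round(object@rowY), collapse = "/"), object@severity,
    object@seed))
})

setMethod("show", "SceneTruth", function(object) {
  cat(sprintf(
    "SceneTruth: severity %d, %d canopy / %d weed / %d noise px\n",
    object@severity, sum(object@canopy), sum(object@weed),
    sum(object@noise)))
})
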