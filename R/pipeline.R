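#' Read a plot image from PNG or JPEG
#'
#' @param path image file path.
#' @param plotId plot identifier; default the file name without
#'   extension.
#' @param mmPerPx ground resolution (default 0.9 mm/px).
#' @return A [PlotImage-class].
#' @export
readPlotImage <- function(path, plotId = NULL, mmPerPx = 0.9) {
  img <- EBImage::readImage(path)
  d <- EBImage::imageData(img)
  if (length(dim(d)) == 2L)
    stop("not a colour image: ", path)
  if (dim(d)[3] > 3L) d <- d[, , 1:3]  # drop alpha
  if (dim(d)[3] != 3L) stop("expected a 3-channel image: ", path)
  px <- aperm(d, c(2, 1, 3))  # EBImage stores x (width) first
  if (is.null(plotId))
    plotId <- sub("\\.[^.]*$", "", basename(path))
  PlotImage(roundHalfUp(px * 255), plotId = plotId, mmPerPx = mmPerPx)
}

#' Write a binary mask as a single-channel PNG (0/255)
#'
#' @param plantMask a [PlantMask-class] or [LineMask-class].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
writeMaskPng <- function(plantMask, path) {
  m <- pixelData(plantMask)
  EBImage::writeImage(EBImage::Image(t(m) * 1), path, type = "png")
  invisible(path)
}

#' Write a scene as PNG
#'
#' @param image a [PlotImage-class].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
writePlotImage <- function(image, path) {
  px <- aperm(image@pixels / 255, c(2, 1, 3))
  EBImage::writeImage(EBImage::Image(px, colormode = "Color"), path,
                      type = "png")
  invisible(path)
}

#' Serialize crop lines to JSON
#'
#' One record per (row, section) with 1-based `y_line` coordinates.
#'
#' @param cropLineMap a [CropLineMap-class].
#' @param path optional output path; if `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to file).
#' @export
cropLinesToJson <- function(cropLineMap, path = NULL) {
  js <- jsonlite::toJSON(cropLines(cropLineMap), dataframe = "rows",
                         auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Diagnostic overlay of the weed-exclusion result
#'
#' Writes an RGB PNG showing retained plant pixels in green, discarded
#' plant pixels in red and the crop-line mask in blue over a dimmed
#' background.
#'
#' @param image a [PlotImage-class].
#' @param opened the opened [PlantMask-class].
#' @param excluded the weed-excluded [PlantMask-class].
#' @param lineMask the [LineMask-class] used for retention.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
writeOverlayPng <- function(image, opened, excluded, lineMask, path) {
  px <- image@pixels / 255 * 0.4
  discarded <- opened@mask & !excluded@mask
  r <- px[, , 1]; g <- px[, , 2]; b <- px[, , 3]
  g[excluded@mask] <- 1; r[excluded@mask] <- 0.1; b[excluded@mask] <- 0.1
  r[discarded] <- 1; g[discarded] <- 0.1; b[discarded] <- 0.1
  b[lineMask@mask] <- 1
  out <- array(c(r, g, b), c(dim(r), 3))
  EBImage::writeImage(EBImage::Image(aperm(out, c(2, 1, 3)),
                                     colormode = "Color"), path,
                      type = "png")
  invisible(path)
}

#' Run the full image-processing pipeline on one plot image
#'
#' Hue conversion, hue-window segmentation, morphological opening,
#' crop-line detection, weed exclusion and colour-feature extraction,
#' with all tunables taken from a [pipelineConfig()] list.
#'
#' @param image a [PlotImage-class].
#' @param config a [pipelineConfig()] list.
#' @return List with `features` ([ColorFeatures-class]), `cropLines`
#'   ([CropLineMap-class]) and the intermediate masks (`raw`, `opened`,
#'   `excluded`) plus the `hue` map.
#' @export
processPlotImage <- function(image, config = pipelineConfig()) {
  hue <- computeHue(image)
  raw <- segmentByHue(hue, config$hue_lo_deg, config$hue_hi_deg)
  opened <- morphologicalOpen(raw, config$open_radius_px)
  lines <- locateCropLines(opened, config$n_sections)
  lm <- buildLineMask(lines, config$line_thickness_px)
  excluded <- excludeWeeds(opened, lm, config$connectivity)
  feats <- extractFeatures(hue, excluded, plotId = plotId(image),
                           edges = config$bin_edges)
  list(features = feats, cropLines = lines, hue = hue, raw = raw,
       opened = opened, excluded = excluded, lineMask = lm)
}

#' Process a directory of plot images into a feature table
#'
#' One row per readable image; unreadable or malformed files are skipped
#' with a warning, not fatal. Crop-line Y positions are appended as
#' diagnostic columns (`y_r<row>_s<section>`).
#'
#' @param imageDir directory of PNG/JPEG plot images.
#' @param config a [pipelineConfig()] list.
#' @return data.frame of features, one row per processed image, ordered
#'   by file name.
#' @export
processImageDir <- function(imageDir, config = pipelineConfig()) {
  files <- sort(list.files(imageDir, pattern = "\\.(png|jpe?g)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (!length(files)) stop("no PNG/JPEG images found in ", imageDir)
  rows <- list()
  for (f in files) {
    res <- tryCatch({
      out <- processPlotImage(readPlotImage(f), config)
      row <- as.data.frame(out$features)
      ln <- cropLines(out$cropLines)
      ys <- stats::setNames(as.list(ln$y_line),
                            sprintf("y_r%d_s%d", ln$row, ln$section))
      cbind(row, as.data.frame(ys))
    }, error = function(e) {
      warning("skipping ", basename(f), ": ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  if (!length(rows)) stop("no image could be processed in ", imageDir)
  do.call(rbind, rows)
}

#' Write a confusion-matrix report CSV
#'
#' 9 x 9 counts (rows = computer score, columns = reference score) with
#' Accuracy I and Accuracy II appended to one decimal place, matching the
#' layout of the published evaluation tables.
#'
#' @param cm a [ConfusionMatrix9-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeConfusionCsv <- function(cm, path) {
  stopifnot(is(cm, "ConfusionMatrix9"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("computer_score", 1:9), collapse = ","), con)
  for (i in 1:9)
    writeLines(paste(c(i, cm@counts[i, ]), collapse = ","), con)
  writeLines(sprintf("Accuracy I,%.1f%%", accuracyI(cm)), con)
  writeLines(sprintf("Accuracy II,%.1f%%", accuracyII(cm)), con)
  invisible(path)
}

#' Read a 9 x 9 confusion matrix from a counts CSV
#'
#' Accepts the layout written by [writeConfusionCsv()] (accuracy footer
#' lines are ignored) or a bare 9-column counts table.
#'
#' @param path CSV path.
#' @return A [ConfusionMatrix9-class].
#' @export
readConfusionCsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^Accuracy", lines)]
  df <- utils::read.csv(text = paste(lines, collapse = "\n"))
  m <- as.matrix(df[, setdiff(names(df), "computer_score"), drop = FALSE])
  if (!identical(dim(m), c(9L, 9L)))
    stop("expected a 9 x 9 counts table in ", path)
  storage.mode(m) <- "integer"
  dimnames(m) <- list(computer = 1:9, reference = 1:9)
  new("ConfusionMatrix9", counts = m)
}

#' Save / load a trained scorer
#'
#' The model is stored as an RDS parameter blob next to a JSON metadata
#' sidecar (method, feature names, hyperparameters, CV grid).
#'
#' @param model an [IdcScorer-class].
#' @param path output `.rds` path (metadata written to `<path>.json`).
#' @return `path`, invisibly.
#' @export
saveScorer <- function(model, path) {
  stopifnot(is(model, "IdcScorer"))
  saveRDS(model, path)
  meta <- list(method = model@method, feature_names = model@featureNames,
               hyperparameters = model@hyper, cv_grid = model@cvTable)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname saveScorer
#' @export
loadScorer <- function(path) {
  model <- readRDS(path)
  stopifnot(is(model, "IdcScorer"))
  model
}
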