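#' Pipeline configuration
#'
#' All tunables of the scoring pipeline in one validated list. Unknown
#' keys are rejected on construction and on file load.
#'
#' @param hue_lo_deg,hue_hi_deg plant segmentation hue window in degrees
#'   (default 40-170).
#' @param open_radius_px disk radius of the morphological opening
#'   (default 2).
#' @param n_sections vertical sections per crop row (default 5).
#' @param line_thickness_px crop-line mask thickness, odd (default 5).
#' @param connectivity pixel connectivity for weed exclusion, 4 or 8
#'   (default 8).
#' @param bin_edges six hue-class boundaries in degrees
#'   (default `c(40, 51, 61, 81, 141, 170)`).
#' @param include_ppc,include_ratio_gc extend the model feature set; see
#'   [defaultFeatureSet()].
#' @param cost_grid,epsilon_grid SVM tuning grids.
#' @param folds CV folds for the SVM grid search (default 10).
#' @param svm_gamma RBF kernel width; `NULL` means `1 / n_features`.
#' @param seed default RNG seed for splits, folds and simulation.
#' @return Named list of class `idc_config`.
#' @export
pipelineConfig <- function(hue_lo_deg = 40, hue_hi_deg = 170,
                           open_radius_px = 2L, n_sections = 5L,
                           line_thickness_px = 5L, connectivity = 8L,
                           bin_edges = c(40, 51, 61, 81, 141, 170),
                           include_ppc = FALSE, include_ratio_gc = FALSE,
                           cost_grid = 2^(-1:7),
                           epsilon_grid = c(0.05, 0.1, 0.2, 0.4, 0.8),
                           folds = 10L, svm_gamma = NULL, seed = 1L) {
  cfg <- list(hue_lo_deg = hue_lo_deg, hue_hi_deg = hue_hi_deg,
              open_radius_px = as.integer(open_radius_px),
              n_sections = as.integer(n_sections),
              line_thickness_px = as.integer(line_thickness_px),
              connectivity = as.integer(connectivity),
              bin_edges = bin_edges, include_ppc = include_ppc,
              include_ratio_gc = include_ratio_gc, cost_grid = cost_grid,
              epsilon_grid = epsilon_grid, folds = as.integer(folds),
              svm_gamma = svm_gamma, seed = as.integer(seed))
  validateConfig(cfg)
  class(cfg) <- "idc_config"
  cfg
}

validateConfig <- function(cfg) {
  known <- names(formals(pipelineConfig))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (!(cfg$hue_lo_deg < cfg$hue_hi_deg) || cfg$hue_lo_deg < 0 ||
      cfg$hue_hi_deg >= 360)
    stop("require 0 <= hue_lo_deg < hue_hi_deg < 360")
  if (cfg$open_radius_px < 1L) stop("open_radius_px must be >= 1")
  if (cfg$line_thickness_px %% 2L == 0L || cfg$line_thickness_px < 1L)
    stop("line_thickness_px must be odd and positive")
  if (!cfg$connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  if (length(cfg$bin_edges) != 6L ||
      is.unsorted(cfg$bin_edges, strictly = TRUE))
    stop("bin_edges must be 6 strictly increasing values")
  if (cfg$folds < 2L) stop("folds must be >= 2")
  invisible(cfg)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Keys absent from the file keep their defaults; unknown keys are an
#' error.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return Config list as from [pipelineConfig()].
#' @export
readPipelineConfig <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(vals)) vals <- list()
  unknown <- setdiff(names(vals), names(formals(pipelineConfig)))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(pipelineConfig, vals)
}
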