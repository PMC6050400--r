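# severity response curves used by the feature-dataset generator.
# own calibration: Ratio_G and PPCF fall steadily with severity, Ratio_YG
# rises to score 4 then flattens, Ratio_Y is most responsive between 3
# and 6 and saturates above 7, Ratio_OY climbs at high severity, and
# Ratio_GC stays small throughout.
severityCurves <- data.frame(
  score    = 1:9,
  ppcf     = c(.36, .32, .28, .24, .20, .16, .12, .08, .04),
  ratio_g  = c(.88, .76, .62, .50, .40, .30, .22, .15, .08),
  ratio_yg = c(.05, .10, .14, .17, .17, .17, .17, .16, .15),
  ratio_y  = c(.02, .04, .08, .15, .22, .27, .29, .30, .30),
  ratio_oy = c(.00, .05, .11, .13, .16, .21, .27, .35, .44),
  ratio_gc = c(.05, .05, .05, .05, .05, .05, .05, .04, .03))

#' Canopy hue-class mixture for a severity score
#'
#' Linear interpolation between a healthy mixture at severity 1 (green
#' dominant) and a severe mixture at severity 9 (orange-yellow dominant),
#' in class order `oy, y, yg, g, gc`. Proportions always sum to 1.
#'
#' @param severity integer in 1..9.
#' @return Named numeric of length 5.
#' @export
severityMixture <- function(severity) {
  stopifnot(severity %in% 1:9)
  lo <- c(oy = 0.00, y = 0.02, yg = 0.05, g = 0.88, gc = 0.05)
  hi <- c(oy = 0.55, y = 0.25, yg = 0.12, g = 0.05, gc = 0.03)
  w <- (severity - 1) / 8
  (1 - w) * lo + w * hi
}

#' Specify a synthetic two-row plot scene
#'
#' Defaults describe a scaled-down overhead plot image: two crop rows
#' parallel to the X axis at 28% and 72% of the image height, canopy as
#' random disks along the row lines with hues drawn from the severity
#' mixture, green off-row weeds kept disconnected from the canopy, soil
#' with hue below the plant segmentation window, and isolated in-window
#' salt noise.
#'
#' @param height,width image size in px (default 192 x 288).
#' @param rowY row centre lines (default `0.28 * height`, `0.72 * height`).
#' @param cover per-row target fraction of columns covered by canopy at
#'   the row line (default 0.5 for both rows).
#' @param severity IDC severity 1-9 (default 3).
#' @param mixture hue-class proportions; default [severityMixture()].
#' @param blobRadius canopy blob radius range in px (default 6-14).
#' @param weedCount number of weed blobs (default 3).
#' @param weedRadius weed blob radius range in px (default 3-6).
#' @param weedMargin minimum distance of weed pixels from either row
#'   line in px (default 25; must exceed half the line-mask thickness).
#' @param soilHue soil hue range in degrees (default 10-35).
#' @param noiseRate fraction of pixels turned into isolated salt noise
#'   (default 0.001).
#' @param seed RNG seed.
#' @return A [SceneSpec-class].
#' @export
sceneSpec <- function(height = 192L, width = 288L,
                      rowY = c(0.28, 0.72) * height,
                      cover = c(0.5, 0.5), severity = 3L,
                      mixture = severityMixture(severity),
                      blobRadius = c(6, 14), weedCount = 3L,
                      weedRadius = c(3, 6), weedMargin = 25,
                      soilHue = c(10, 35), noiseRate = 0.001,
                      seed = 1L) {
  new("SceneSpec", height = as.integer(height), width = as.integer(width),
      rowY = rowY, cover = rep_len(cover, 2L), severity = as.integer(severity),
      mixture = mixture, blobRadius = blobRadius,
      weedCount = as.integer(weedCount), weedRadius = weedRadius,
      weedMargin = weedMargin, soilHue = soilHue, noiseRate = noiseRate,
      seed = as.integer(seed))
}

# paint a disk into a logical matrix
paintDisk <- function(m, cy, cx, r) {
  H <- nrow(m); W <- ncol(m)
  ys <- max(1L, floor(cy - r)):min(H, ceiling(cy + r))
  xs <- max(1L, floor(cx - r)):min(W, ceiling(cx + r))
  sub <- outer(ys - cy, xs - cx, function(a, b) a^2 + b^2) <= r^2
  m[ys, xs] <- m[ys, xs] | sub
  m
}

# chebyshev dilation of a logical matrix by `d` pixels
boxDilate <- function(m, d) {
  if (!any(m)) return(m)
  k <- matrix(1, 2L * d + 1L, 2L * d + 1L)
  EBImage::dilate(m * 1, k) > 0.5
}

# hue class intervals shrunk 1 degree from each edge, so 8-bit RGB
# round-trips cannot move a drawn hue across a class boundary
classHueRange <- list(oy = c(41, 50), y = c(52, 60), yg = c(62, 80),
                      g = c(82, 140), gc = c(142, 169))

hsvToRgbInt <- function(h, s, v) {
  grDevices::col2rgb(grDevices::hsv(h / 360, s, v))
}

#' Generate a synthetic plot scene with ground truth
#'
#' Renders the scene described by a [SceneSpec-class]: soil background,
#' canopy disks centred on the two row lines with per-pixel hues drawn
#' from the severity mixture, weed disks placed at least `weedMargin`
#' from both row lines and disconnected from the canopy, and isolated
#' salt-noise pixels of in-window hue. Deterministic given the spec's
#' seed.
#'
#' @param spec a [SceneSpec-class].
#' @return List with elements `image` ([PlotImage-class]) and `truth`
#'   ([SceneTruth-class]).
#' @export
generateScene <- function(spec) {
  stopifnot(is(spec, "SceneSpec"))
  H <- spec@height; W <- spec@width
  withSeed(spec@seed, {
    # canopy blobs are laid down until every fifth of the row reaches the
    # cover target at the row line, emulating a continuous planted row
    # rather than isolated clumps
    canopy <- matrix(FALSE, H, W)
    nBands <- 5L
    bounds <- sectionBounds(W, nBands)
    for (r in 1:2) {
      if (spec@cover[r] <= 0) next
      rowLine <- roundHalfUp(spec@rowY[r])
      for (i in seq_len(1000L)) {
        covered <- vapply(seq_len(nBands), function(s)
          mean(canopy[rowLine, bounds[s, 1]:bounds[s, 2]]), numeric(1))
        short <- which(covered < spec@cover[r])
        if (!length(short)) break
        s <- short[which.min(covered[short])]
        cx <- stats::runif(1, bounds[s, 1], bounds[s, 2])
        cy <- spec@rowY[r] + stats::runif(1, -1, 1)  # planting wobble
        rad <- stats::runif(1, spec@blobRadius[1], spec@blobRadius[2])
        canopy <- paintDisk(canopy, cy, cx, rad)
      }
    }

    weed <- matrix(FALSE, H, W)
    if (spec@weedCount > 0L) {
      forbidden <- boxDilate(canopy, 2L)  # keep weeds 8-disconnected
      placed <- 0L
      for (att in seq_len(500L)) {
        if (placed >= spec@weedCount) break
        rad <- stats::runif(1, spec@weedRadius[1], spec@weedRadius[2])
        cy <- stats::runif(1, 1 + rad, H - rad)
        if (min(abs(cy - spec@rowY)) < spec@weedMargin + rad) next
        cx <- stats::runif(1, 1 + rad, W - rad)
        cand <- paintDisk(matrix(FALSE, H, W), cy, cx, rad)
        if (any(cand & forbidden)) next
        weed <- weed | cand
        placed <- placed + 1L
      }
      if (placed < spec@weedCount)
        stop("infeasible weed placement: margin/size constraints unmet")
    }

    soil <- !(canopy | weed)

    # soil background
    nPix <- H * W
    hue <- matrix(stats::runif(nPix, spec@soilHue[1], spec@soilHue[2]), H, W)
    sat <- matrix(stats::runif(nPix, 0.30, 0.50), H, W)
    val <- matrix(stats::runif(nPix, 0.35, 0.55), H, W)

    # weeds: green foliage
    nw <- sum(weed)
    if (nw) {
      hue[weed] <- stats::runif(nw, 95, 135)
      sat[weed] <- stats::runif(nw, 0.60, 0.80)
      val[weed] <- stats::runif(nw, 0.55, 0.75)
    }

    # canopy: hues from the severity mixture
    nc <- sum(canopy)
    realized <- stats::setNames(numeric(5), names(spec@mixture))
    if (nc) {
      cls <- sample(names(spec@mixture), nc, replace = TRUE,
                    prob = spec@mixture)
      lo <- vapply(classHueRange, `[`, numeric(1), 1)[cls]
      hi <- vapply(classHueRange, `[`, numeric(1), 2)[cls]
      hue[canopy] <- stats::runif(nc, lo, hi)
      sat[canopy] <- stats::runif(nc, 0.60, 0.80)
      val[canopy] <- stats::runif(nc, 0.55, 0.75)
      tab <- table(factor(cls, levels = names(spec@mixture)))
      realized <- stats::setNames(as.numeric(tab) / nc, names(spec@mixture))
    }

    # isolated salt noise on soil, away from plants and from each other
    noise <- matrix(FALSE, H, W)
    k <- roundHalfUp(spec@noiseRate * nPix)
    if (k > 0) {
      eligible <- which(!boxDilate(canopy | weed, 2L))
      cand <- sample(eligible, min(length(eligible), 20L * k))
      for (i in cand) {
        if (sum(noise) >= k) break
        r0 <- (i - 1L) %% H + 1L; c0 <- (i - 1L) %/% H + 1L
        ys <- max(1L, r0 - 2L):min(H, r0 + 2L)
        xs <- max(1L, c0 - 2L):min(W, c0 + 2L)
        if (any(noise[ys, xs])) next
        noise[r0, c0] <- TRUE
        hue[r0, c0] <- stats::runif(1, 45, 165)
        sat[r0, c0] <- stats::runif(1, 0.60, 0.80)
        val[r0, c0] <- stats::runif(1, 0.55, 0.75)
      }
    }

    rgb <- hsvToRgbInt(as.vector(hue), as.vector(sat), as.vector(val))
    px <- array(0L, c(H, W, 3))
    px[, , 1] <- rgb[1, ]; px[, , 2] <- rgb[2, ]; px[, , 3] <- rgb[3, ]

    list(image = PlotImage(px, plotId = sprintf("synthetic_s%d_seed%d",
                                                spec@severity, spec@seed)),
         truth = new("SceneTruth", canopy = canopy, weed = weed,
                     soil = soil, noise = noise, rowY = spec@rowY,
                     severity = spec@severity,
                     realizedProportions = realized))
  })
}

#' Generate a synthetic scored feature dataset
#'
#' Draws per-plot scores from `scoreDist`, sets the expected features
#' from the severity response curves (`severityCurves`), adds truncated
#' Gaussian noise and renormalizes the five class fractions to sum to 1.
#' Emits a field score (`fs`) plus a correlated office score
#' (`os = fs` shifted by symmetric integer noise, clipped to 1-9).
#' With `noiseSd = 0` features are exact deterministic functions of the
#' score.
#'
#' @param n number of plots.
#' @param scoreDist probabilities over scores 1..9 (default uniform).
#' @param noiseSd Gaussian noise standard deviation on each feature
#'   (default 0.03).
#' @param osShiftProbs probabilities of office-score offsets
#'   `-2..2` (default `c(0.025, 0.175, 0.6, 0.175, 0.025)`).
#' @param seed RNG seed.
#' @return data.frame with columns `plot_id`, `ppc`, `ppcf`, `ratio_gc`,
#'   `ratio_g`, `ratio_yg`, `ratio_y`, `ratio_oy`, `fs`, `os`.
#' @export
generateFeatureDataset <- function(n, scoreDist = rep(1 / 9, 9),
                                   noiseSd = 0.03,
                                   osShiftProbs = c(0.025, 0.175, 0.6,
                                                    0.175, 0.025),
                                   seed = 1L) {
  stopifnot(n >= 1, noiseSd >= 0, length(scoreDist) == 9)
  withSeed(seed, {
    fs <- sample(1:9, n, replace = TRUE, prob = scoreDist)
    mu <- severityCurves[fs, ]
    ratioCols <- c("ratio_oy", "ratio_y", "ratio_yg", "ratio_g", "ratio_gc")
    R <- as.matrix(mu[, ratioCols])
    if (noiseSd > 0) {
      R <- R + matrix(stats::rnorm(length(R), 0, noiseSd),
                      nrow(R), ncol(R))
      R[R < 0] <- 0  # truncate at zero before renormalizing
    }
    rs <- rowSums(R)
    zero <- rs == 0
    if (any(zero)) { R[zero, ] <- as.matrix(mu[zero, ratioCols]); rs[zero] <- 1 }
    R <- R / rowSums(R)
    ppcf <- mu$ppcf
    if (noiseSd > 0)
      ppcf <- pmin(1, pmax(0.001, ppcf + stats::rnorm(n, 0, noiseSd)))
    shift <- sample(-2:2, n, replace = TRUE, prob = osShiftProbs)
    os <- pmin(9L, pmax(1L, fs + shift))
    data.frame(plot_id = sprintf("plot%04d", seq_len(n)),
               ppc = as.integer(roundHalfUp(ppcf * 2304 * 1536)),
               ppcf = ppcf,
               ratio_gc = R[, "ratio_gc"], ratio_g = R[, "ratio_g"],
               ratio_yg = R[, "ratio_yg"], ratio_y = R[, "ratio_y"],
               ratio_oy = R[, "ratio_oy"], fs = as.integer(fs),
               os = as.integer(os))
  })
}
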