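#' Split a plant mask into the two row halves
#'
#' The two-row plot image is cut horizontally in half: the top half holds
#' rows `1..floor(H/2)`, the bottom half the rest (for odd heights the
#' extra row goes to the bottom half). No pixels are lost or duplicated.
#'
#' @param plantMask a [PlantMask-class].
#' @return List with elements `top` and `bottom`, both [PlantMask-class]
#'   objects sharing the input's provenance.
#' @export
splitRows <- function(plantMask) {
  stopifnot(is(plantMask, "PlantMask"))
  H <- nrow(plantMask@mask)
  if (H < 2L) stop("mask must have at least 2 rows")
  cut <- H %/% 2L
  list(
    top = new("PlantMask", mask = plantMask@mask[seq_len(cut), , drop = FALSE],
              provenance = plantMask@provenance),
    bottom = new("PlantMask",
                 mask = plantMask@mask[(cut + 1L):H, , drop = FALSE],
                 provenance = plantMask@provenance))
}

# section column boundaries: equal width, remainder columns to the last
sectionBounds <- function(W, nSections) {
  w <- W %/% nSections
  xs <- (seq_len(nSections) - 1L) * w + 1L
  xe <- xs + w - 1L
  xe[nSections] <- W
  cbind(x_start = xs, x_end = xe)
}

#' Locate the crop lines of a two-row plot
#'
#' Each half-image is divided into `nSections` equal-width vertical
#' sections (remainder columns go to the last section). Within a section
#' the plant pixels are summed along the X direction and the crop line is
#' placed at the Y position with the maximum count; if the maximum is
#' attained at several Y positions, the first and last maximizing Y are
#' averaged (rounded half-up). A section with no plant pixels at all
#' falls back to its vertical centre, with a warning.
#'
#' @param plantMask an opened [PlantMask-class].
#' @param nSections number of vertical sections per row (default 5).
#' @return A [CropLineMap-class]; `y_line` values are 1-based full-image
#'   pixel rows.
#' @export
locateCropLines <- function(plantMask, nSections = 5L) {
  stopifnot(is(plantMask, "PlantMask"))
  if (plantMask@provenance != "opened")
    stop("locateCropLines expects an opened mask")
  H <- nrow(plantMask@mask); W <- ncol(plantMask@mask)
  if (nSections < 1L || nSections > W)
    stop("nSections must be in [1, image width]")
  halves <- splitRows(plantMask)
  cut <- H %/% 2L
  bounds <- sectionBounds(W, as.integer(nSections))
  res <- vector("list", 2L * nSections)
  for (r in 1:2) {
    half <- if (r == 1L) halves$top@mask else halves$bottom@mask
    yOff <- if (r == 1L) 0L else cut
    for (s in seq_len(nSections)) {
      band <- half[, bounds[s, 1]:bounds[s, 2], drop = FALSE]
      counts <- rowSums(band)
      if (all(counts == 0)) {
        warning(sprintf(
          "row %d section %d has no plant pixels; crop line set to band centre",
          r, s))
        y <- roundHalfUp((1 + nrow(half)) / 2)
      } else {
        hits <- which(counts == max(counts))
        y <- roundHalfUp((hits[1] + hits[length(hits)]) / 2)
      }
      res[[(r - 1L) * nSections + s]] <- data.frame(
        row = r, section = s, x_start = bounds[s, 1], x_end = bounds[s, 2],
        y_line = as.integer(y + yOff))
    }
  }
  new("CropLineMap", lines = do.call(rbind, res), dim = c(H, W))
}

#' Build a thin line-shaped seed mask from crop lines
#'
#' For each section, pixels within `(thicknessPx - 1) / 2` rows of that
#' section's crop line (and inside its column range) are set. The line
#' mask seeds the retention step of [excludeWeeds()].
#'
#' @param cropLineMap a [CropLineMap-class].
#' @param thicknessPx odd line thickness in pixels (default 5).
#' @return A [LineMask-class] on the full image grid.
#' @export
buildLineMask <- function(cropLineMap, thicknessPx = 5L) {
  stopifnot(is(cropLineMap, "CropLineMap"))
  thicknessPx <- as.integer(thicknessPx)
  if (thicknessPx < 1L || thicknessPx %% 2L == 0L)
    stop("thicknessPx must be an odd positive integer")
  H <- cropLineMap@dim[1]; W <- cropLineMap@dim[2]
  half <- (thicknessPx - 1L) %/% 2L
  m <- matrix(FALSE, H, W)
  ln <- cropLineMap@lines
  for (i in seq_len(nrow(ln))) {
    ys <- max(1L, ln$y_line[i] - half):min(H, ln$y_line[i] + half)
    m[ys, ln$x_start[i]:ln$x_end[i]] <- TRUE
  }
  new("LineMask", mask = m, thicknessPx = thicknessPx)
}

# label connected components of a logical matrix; 4- or 8-connectivity.
# returns an integer matrix, 0 = background
labelComponents <- function(mask, connectivity = 8L) {
  H <- nrow(mask); W <- ncol(mask)
  n <- sum(mask)
  lab <- matrix(0L, H, W)
  if (n == 0L) return(lab)
  lab[mask] <- seq_len(n)
  offs <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  edges <- list()
  for (o in offs) {
    dr <- o[1]; dc <- o[2]
    r1 <- max(1L, 1L - dr):min(H, H - dr)
    c1 <- max(1L, 1L - dc):min(W, W - dc)
    a <- lab[r1, c1, drop = FALSE]
    b <- lab[r1 + dr, c1 + dc, drop = FALSE]
    sel <- a > 0L & b > 0L
    if (any(sel)) edges[[length(edges) + 1L]] <- cbind(a[sel], b[sel])
  }
  if (length(edges)) {
    g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
  } else comp <- seq_len(n)
  lab[mask] <- comp[lab[mask]]
  lab
}

#' Exclude weeds by crop-line connectivity
#'
#' Plant pixels lying on the line mask are taken as "centre plant
#' pixels"; every plant pixel connected to a centre pixel is retained and
#' all other plant pixels (weeds and any remaining speckle) are
#' discarded. Retention runs on the full-image mask so a plant spanning
#' the half-image cut is kept whole.
#'
#' @param plantMask an opened [PlantMask-class].
#' @param lineMask a [LineMask-class] on the same grid.
#' @param connectivity pixel connectivity, 4 or 8 (default 8 so
#'   diagonally touching leaflets count as connected).
#' @return A [PlantMask-class] with provenance `"weed_excluded"`; always
#'   a subset of the input.
#' @export
excludeWeeds <- function(plantMask, lineMask, connectivity = 8L) {
  stopifnot(is(plantMask, "PlantMask"), is(lineMask, "LineMask"))
  if (!identical(dim(plantMask@mask), dim(lineMask@mask)))
    stop("plant mask and line mask must share dimensions")
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  lab <- labelComponents(plantMask@mask, as.integer(connectivity))
  seeds <- unique(lab[plantMask@mask & lineMask@mask])
  keep <- matrix(lab %in% seeds[seeds > 0L], nrow(lab), ncol(lab))
  new("PlantMask", mask = keep & plantMask@mask,
      provenance = "weed_excluded")
}
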