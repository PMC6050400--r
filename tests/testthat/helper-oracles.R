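# brute-force reference implementations used as independent oracles.
# all of them are deliberately naive (per-pixel loops, explicit queues)
# and share only the operation *definitions* with the package code.

# per-pixel RGB -> hue in degrees; NA where chroma is zero
oracleHuePixel <- function(r, g, b) {
  M <- max(r, g, b); m <- min(r, g, b); C <- M - m
  if (C == 0) return(NA_real_)
  h <- if (M == r) ((g - b) / C) %% 6
  else if (M == g) (b - r) / C + 2
  else (r - g) / C + 4
  (60 * h) %% 360
}

# hue-window plant rule applied pixel by pixel
oracleSegment <- function(pixels, lo = 40, hi = 170) {
  H <- dim(pixels)[1]; W <- dim(pixels)[2]
  out <- matrix(FALSE, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    h <- oracleHuePixel(pixels[i, j, 1], pixels[i, j, 2], pixels[i, j, 3])
    out[i, j] <- !is.na(h) && h >= lo && h <= hi
  }
  out
}

# sliding-window binary erosion/dilation with an explicit kernel.
# out-of-image counts as foreground for erosion and background for
# dilation, so a mask touching the border behaves as if continued.
oracleErode <- function(m, kern) {
  H <- nrow(m); W <- ncol(m); r <- (nrow(kern) - 1L) %/% 2L
  out <- matrix(FALSE, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    ok <- TRUE
    for (di in -r:r) {
      for (dj in -r:r) {
        if (!kern[di + r + 1L, dj + r + 1L]) next
        ii <- i + di; jj <- j + dj
        if (ii < 1L || ii > H || jj < 1L || jj > W) next
        if (!m[ii, jj]) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    out[i, j] <- ok
  }
  out
}

oracleDilate <- function(m, kern) {
  H <- nrow(m); W <- ncol(m); r <- (nrow(kern) - 1L) %/% 2L
  out <- matrix(FALSE, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    hit <- FALSE
    for (di in -r:r) {
      for (dj in -r:r) {
        if (!kern[di + r + 1L, dj + r + 1L]) next
        ii <- i + di; jj <- j + dj
        if (ii < 1L || ii > H || jj < 1L || jj > W) next
        if (m[ii, jj]) { hit <- TRUE; break }
      }
      if (hit) break
    }
    out[i, j] <- hit
  }
  out
}

oracleOpen <- function(m, kern) oracleDilate(oracleErode(m, kern), kern)

# per-band arg-max-with-tie-averaging crop-line search on one half-image
oracleCropLines <- function(halfMask, nSections) {
  W <- ncol(halfMask)
  w <- W %/% nSections
  ys <- integer(nSections)
  for (s in seq_len(nSections)) {
    x0 <- (s - 1L) * w + 1L
    x1 <- if (s == nSections) W else x0 + w - 1L
    counts <- vapply(seq_len(nrow(halfMask)),
                     function(y) sum(halfMask[y, x0:x1]), numeric(1))
    if (all(counts == 0)) {
      ys[s] <- as.integer(floor((1 + nrow(halfMask)) / 2 + 0.5))
    } else {
      hits <- which(counts == max(counts))
      ys[s] <- as.integer(floor((hits[1] + hits[length(hits)]) / 2 + 0.5))
    }
  }
  ys
}

# per-pixel distance check for the thin line mask
oracleLineMask <- function(lines, H, W, thickness) {
  out <- matrix(FALSE, H, W)
  half <- (thickness - 1L) %/% 2L
  for (i in seq_len(H)) for (j in seq_len(W)) {
    for (k in seq_len(nrow(lines))) {
      if (j >= lines$x_start[k] && j <= lines$x_end[k] &&
          abs(i - lines$y_line[k]) <= half) {
        out[i, j] <- TRUE
        break
      }
    }
  }
  out
}

# BFS flood fill from the line-mask seed pixels
oracleFloodFill <- function(mask, seedMask, connectivity = 8L) {
  H <- nrow(mask); W <- ncol(mask)
  offs <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8L)
    offs <- rbind(offs, c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  visited <- matrix(FALSE, H, W)
  queue <- which(mask & seedMask)
  visited[queue] <- TRUE
  while (length(queue)) {
    q <- queue[1]; queue <- queue[-1]
    i <- (q - 1L) %% H + 1L; j <- (q - 1L) %/% H + 1L
    for (k in seq_len(nrow(offs))) {
      ii <- i + offs[k, 1]; jj <- j + offs[k, 2]
      if (ii < 1L || ii > H || jj < 1L || jj > W) next
      if (mask[ii, jj] && !visited[ii, jj]) {
        visited[ii, jj] <- TRUE
        queue <- c(queue, (jj - 1L) * H + ii)
      }
    }
  }
  visited
}

# nested-loop confusion tally
oracleConfusion <- function(predicted, reference) {
  out <- matrix(0L, 9, 9)
  for (k in seq_along(predicted))
    out[predicted[k], reference[k]] <- out[predicted[k], reference[k]] + 1L
  out
}

# random sparse logical matrix with a few blobs, for oracle runs
randomBlobMask <- function(H, W, nBlobs = 5L, maxR = 4) {
  m <- matrix(FALSE, H, W)
  for (b in seq_len(nBlobs)) {
    cy <- runif(1, 1, H); cx <- runif(1, 1, W); r <- runif(1, 1, maxR)
    ys <- max(1, floor(cy - r)):min(H, ceiling(cy + r))
    xs <- max(1, floor(cx - r)):min(W, ceiling(cx + r))
    sub <- outer(ys - cy, xs - cx, function(a, b) a^2 + b^2) <= r^2
    m[ys, xs] <- m[ys, xs] | sub
  }
  m
}

# random 8-bit RGB image as a PlotImage-compatible array
randomRgbArray <- function(H, W) {
  array(sample(0:255, H * W * 3, replace = TRUE), c(H, W, 3))
}

asPlantMask <- function(m, provenance = "opened") {
  new("PlantMask", mask = m, provenance = provenance)
}

benchmarkConfusion <- function(name) {
  readConfusionCsv(system.file(
    "extdata", sprintf("benchmark_confusion_%s.csv", name),
    package = "idcscore"))
}
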