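test_that("row split halves the image without losing pixels", {
  set.seed(201)
  m <- matrix(runif(10 * 8) < 0.4, 10, 8)
  h <- splitRows(asPlantMask(m))
  expect_identical(dim(pixelData(h$top)), c(5L, 8L))
  expect_identical(dim(pixelData(h$bottom)), c(5L, 8L))

  m2 <- matrix(runif(11 * 8) < 0.4, 11, 8)
  h2 <- splitRows(asPlantMask(m2))
  expect_identical(dim(pixelData(h2$top)), c(5L, 8L))   # extra row goes down
  expect_identical(dim(pixelData(h2$bottom)), c(6L, 8L))
  expect_identical(sum(pixelData(h2$top)) + sum(pixelData(h2$bottom)),
                   sum(m2))
  expect_identical(rbind(pixelData(h2$top), pixelData(h2$bottom)), m2)
})

test_that("crop line sits at the maximum of the column sums", {
  m <- matrix(FALSE, 80, 50)
  m[37, ] <- TRUE          # top half row
  m[65, ] <- TRUE          # bottom half row
  clm <- locateCropLines(asPlantMask(m), nSections = 5)
  ln <- cropLines(clm)
  expect_identical(ln$y_line[ln$row == 1], rep(37L, 5))
  expect_identical(ln$y_line[ln$row == 2], rep(65L, 5))
})

test_that("multiple maxima are tie-averaged between first and last", {
  m <- matrix(FALSE, 60, 10)
  m[10, ] <- TRUE
  m[20, ] <- TRUE          # equal full-cover maxima at y = 10 and 20
  m[45, ] <- TRUE          # unique maximum in the bottom half
  ln <- cropLines(locateCropLines(asPlantMask(m), nSections = 1))
  expect_identical(ln$y_line[ln$row == 1], 15L)
  expect_identical(ln$y_line[ln$row == 2], 45L)
})

test_that("an empty band falls back to its centre with a warning", {
  m <- matrix(FALSE, 40, 20)
  m[30, ] <- TRUE          # only the bottom half has plants
  expect_warning(clm <- locateCropLines(asPlantMask(m), nSections = 1),
                 "no plant pixels")
  ln <- cropLines(clm)
  expect_identical(ln$y_line[ln$row == 1], 11L)  # centre of rows 1..20
  expect_identical(ln$y_line[ln$row == 2], 30L)
  expect_error(locateCropLines(asPlantMask(m), nSections = 0))
  expect_error(locateCropLines(asPlantMask(m), nSections = 21))
})

test_that("crop-line location matches the exhaustive per-band oracle", {
  set.seed(202)
  for (rep in 1:20) {
    m <- randomBlobMask(40, 50, nBlobs = 10L)
    m[1, 1] <- TRUE; m[40, 50] <- TRUE   # keep every band non-degenerate
    got <- cropLines(suppressWarnings(
      locateCropLines(asPlantMask(m), nSections = 5)))
    top <- oracleCropLines(m[1:20, , drop = FALSE], 5L)
    bot <- oracleCropLines(m[21:40, , drop = FALSE], 5L) + 20L
    expect_identical(got$y_line, c(top, bot))
  }
})

test_that("line mask geometry matches its definition", {
  m <- matrix(FALSE, 30, 20); m[12, ] <- TRUE; m[25, ] <- TRUE
  clm <- locateCropLines(asPlantMask(m), nSections = 2)

  lm1 <- buildLineMask(clm, thicknessPx = 1)
  rows <- unname(which(pixelData(lm1), arr.ind = TRUE)[, "row"])
  expect_identical(sort(rows), rep(c(12L, 25L), each = 20))

  lm5 <- buildLineMask(clm, thicknessPx = 5)
  expect_identical(sum(pixelData(lm5)), 2L * 5L * 20L)
  expect_identical(pixelData(lm5),
                   oracleLineMask(cropLines(clm), 30L, 20L, 5L))
  expect_error(buildLineMask(clm, thicknessPx = 4))
})

test_that("only components touching the crop line are retained", {
  m <- matrix(FALSE, 30, 30)
  m[8:14, 5:12] <- TRUE        # blob crossing the line at y = 10
  m[22:26, 20:25] <- TRUE      # off-line blob
  lines <- data.frame(row = 1L, section = 1L, x_start = 1L, x_end = 30L,
                      y_line = 10L)
  lm <- buildLineMask(new("CropLineMap", lines = lines,
                          dim = c(30L, 30L)), 5L)
  kept <- excludeWeeds(asPlantMask(m), lm)
  expect_identical(maskProvenance(kept), "weed_excluded")
  expect_true(all(pixelData(kept)[8:14, 5:12]))
  expect_false(any(pixelData(kept)[22:26, 20:25]))

  empty <- new("LineMask", mask = matrix(FALSE, 30, 30), thicknessPx = 5L)
  expect_false(any(pixelData(excludeWeeds(asPlantMask(m), empty))))
  expect_error(excludeWeeds(asPlantMask(m),
                            new("LineMask", mask = matrix(FALSE, 10, 10),
                                thicknessPx = 5L)))
})

test_that("weed exclusion equals a BFS flood fill from the line pixels", {
  set.seed(203)
  lines <- data.frame(row = 1L, section = 1L, x_start = 1L, x_end = 48L,
                      y_line = 16L)
  lm <- buildLineMask(new("CropLineMap", lines = lines,
                          dim = c(48L, 48L)), 5L)
  for (conn in c(4L, 8L)) {
    for (rep in 1:10) {
      m <- randomBlobMask(48, 48, nBlobs = 12L)
      got <- pixelData(excludeWeeds(asPlantMask(m), lm, connectivity = conn))
      expect_identical(got, oracleFloodFill(m, pixelData(lm), conn))
    }
  }
})

test_that("diagonal touches connect under 8- but not 4-connectivity", {
  m <- matrix(FALSE, 10, 10)
  m[5, 5] <- TRUE; m[6, 6] <- TRUE
  seed <- new("LineMask", mask = matrix(FALSE, 10, 10), thicknessPx = 1L)
  sm <- pixelData(seed); sm[5, 5] <- TRUE
  seed@mask <- sm
  expect_identical(sum(pixelData(excludeWeeds(asPlantMask(m), seed, 8L))), 2L)
  expect_identical(sum(pixelData(excludeWeeds(asPlantMask(m), seed, 4L))), 1L)
})

test_that("weed exclusion is idempotent and component-consistent", {
  set.seed(204)
  lines <- data.frame(row = 1L, section = 1L, x_start = 1L, x_end = 40L,
                      y_line = 13L)
  lm <- buildLineMask(new("CropLineMap", lines = lines,
                          dim = c(40L, 40L)), 5L)
  for (rep in 1:5) {
    m <- randomBlobMask(40, 40, nBlobs = 10L)
    k1 <- excludeWeeds(asPlantMask(m), lm)
    expect_true(all(pixelData(k1) <= m))
    k2 <- excludeWeeds(k1, lm)
    expect_identical(pixelData(k2), pixelData(k1))
    # every retained component touches the lines, every discarded one not
    lab <- idcscore:::labelComponents(m, 8L)
    for (cid in setdiff(unique(as.vector(lab)), 0L)) {
      comp <- lab == cid
      touches <- any(comp & pixelData(lm))
      retained <- any(comp & pixelData(k1))
      expect_identical(retained, touches)
    }
  }
})
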