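test_that("scene generation is deterministic and severity-faithful", {
  a <- generateScene(sceneSpec(severity = 4L, seed = 9))
  b <- generateScene(sceneSpec(severity = 4L, seed = 9))
  expect_identical(a$image@pixels, b$image@pixels)
  expect_identical(a$truth@canopy, b$truth@canopy)

  healthy <- generateScene(sceneSpec(severity = 1L, seed = 10))
  expect_gte(healthy$truth@realizedProportions[["g"]], 0.7)

  # ground-truth masks partition the image
  tr <- a$truth
  expect_true(all(tr@canopy + tr@weed + tr@soil == 1))
  expect_true(all(tr@noise <= tr@soil))
})

test_that("a weed-free noiseless scene segments to the exact canopy", {
  sc <- generateScene(sceneSpec(severity = 3L, weedCount = 0L,
                                noiseRate = 0, seed = 11))
  out <- processPlotImage(sc$image)
  # raw segmentation recovers the canopy pixel-for-pixel (all canopy hues
  # are inside the window, all soil hues outside)
  expect_identical(pixelData(out$raw), sc$truth@canopy)
  # weed exclusion removes nothing when there is nothing to remove
  expect_identical(pixelData(out$excluded), pixelData(out$opened))
})

test_that("pipeline recovers realized canopy hue proportions with weeds present", {
  for (seed in 12:14) {
    sc <- generateScene(sceneSpec(severity = 5L, seed = seed))
    out <- processPlotImage(sc$image)
    got <- out$features@ratios
    want <- sc$truth@realizedProportions
    for (cls in c("oy", "y", "yg", "g", "gc"))
      expect_lt(abs(got[[paste0("ratio_", cls)]] - want[[cls]]), 0.02)
  }
})

test_that("crop lines are recovered near the true rows at default cover", {
  for (seed in 15:19) {
    sc <- generateScene(sceneSpec(seed = seed))
    ln <- cropLines(processPlotImage(sc$image)$cropLines)
    err <- abs(ln$y_line - rep(sc$truth@rowY, each = 5))
    expect_lte(max(err), 2)
  }
})

test_that("infeasible weed placement errors out", {
  expect_error(generateScene(sceneSpec(height = 60L, weedMargin = 100,
                                       seed = 1)),
               "infeasible")
})

test_that("feature datasets follow the severity curves", {
  d0 <- generateFeatureDataset(50, noiseSd = 0, seed = 41)
  curves <- idcscore:::severityCurves
  expect_identical(d0$ppcf, curves$ppcf[d0$fs])
  expect_identical(d0$ratio_g, curves$ratio_g[d0$fs])

  d <- generateFeatureDataset(400, seed = 42)
  rs <- rowSums(d[, c("ratio_gc", "ratio_g", "ratio_yg", "ratio_y",
                      "ratio_oy")])
  expect_true(all(abs(rs - 1) < 1e-9))
  expect_true(all(d$fs %in% 1:9) && all(d$os %in% 1:9))
  # office score stays close to field score by construction
  expect_true(all(abs(d$os - d$fs) <= 2))
  expect_gt(cor(d$os, d$fs), 0.9)

  # determinism
  expect_identical(d, generateFeatureDataset(400, seed = 42))
})

test_that("sample means track the severity curves at large n", {
  d <- generateFeatureDataset(5000, seed = 43)
  m1 <- mean(d$ratio_g[d$fs == 1])
  expect_lt(abs(m1 - idcscore:::severityCurves$ratio_g[1]), 0.02)
  m9 <- mean(d$ratio_oy[d$fs == 9])
  expect_lt(abs(m9 - idcscore:::severityCurves$ratio_oy[9]), 0.02)
})

test_that("accuracy degrades as feature noise grows", {
  accAt <- function(noiseSd) {
    d <- generateFeatureDataset(600, noiseSd = noiseSd, seed = 44)
    sp <- splitTrainTest(d, seed = 44)
    accuracyI(evaluateScorer(trainLdaScorer(sp$train), sp$test))
  }
  a <- vapply(c(0.01, 0.06, 0.15), accAt, numeric(1))
  expect_true(a[1] > a[2] && a[2] > a[3])
})
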