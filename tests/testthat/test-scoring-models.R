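makeGaussianData <- function(n, means, sdev = 0.5, seed = 1) {
  set.seed(seed)
  k <- nrow(means)
  cls <- sample(seq_len(k), n, replace = TRUE)
  X <- means[cls, , drop = FALSE] +
    matrix(rnorm(n * ncol(means), 0, sdev), n, ncol(means))
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(means)))
  df$fs <- cls
  df
}

test_that("train/test split is equal, disjoint and reproducible", {
  d <- data.frame(f1 = rnorm(1530), fs = rep(1:9, length.out = 1530))
  sp <- splitTrainTest(d, seed = 11)
  expect_identical(nrow(sp$train), 765L)
  expect_identical(nrow(sp$test), 765L)
  expect_length(intersect(rownames(sp$train), rownames(sp$test)), 0)

  d5 <- d[1:5, ]
  sp5 <- splitTrainTest(d5, seed = 2)
  expect_identical(nrow(sp5$train), 3L)   # odd n: extra row trains
  expect_identical(nrow(sp5$test), 2L)

  sp2 <- splitTrainTest(d, seed = 11)
  expect_identical(sp$train, sp2$train)
  sp3 <- splitTrainTest(d, seed = 12)
  expect_false(identical(sp$train, sp3$train))
  expect_error(splitTrainTest(d[1, , drop = FALSE]))
})

test_that("LDA separates well-separated classes and is label-symmetric", {
  d <- makeGaussianData(200, matrix(c(0, 10), 2, 1), sdev = 0.1, seed = 21)
  sp <- splitTrainTest(d, seed = 1)
  m <- trainLdaScorer(sp$train, "f1")
  expect_identical(predictScore(m, sp$test), as.integer(sp$test$fs))

  # swapping class labels swaps predictions, not the boundary
  dSwap <- d; dSwap$fs <- 3L - d$fs
  mSwap <- trainLdaScorer(splitTrainTest(dSwap, seed = 1)$train, "f1")
  expect_identical(predictScore(mSwap, sp$test), 3L - predictScore(m, sp$test))

  dOne <- d; dOne$fs <- 1L
  expect_error(trainLdaScorer(dOne, "f1"), "single class")
})

test_that("LDA predictions equal the brute-force discriminant oracle", {
  d <- makeGaussianData(150, matrix(c(0, 2, 4, 1, 0, 3), 3, 2), sdev = 0.8,
                        seed = 22)
  m <- trainLdaScorer(d, c("f1", "f2"))
  X <- as.matrix(d[, c("f1", "f2")])
  f <- m@fit
  oracle <- apply(X, 1, function(x) {
    post <- vapply(seq_along(f$classes), function(k) {
      mu <- f$means[k, ]
      drop(x %*% f$covInv %*% mu - 0.5 * mu %*% f$covInv %*% mu +
             f$logPriors[k])
    }, numeric(1))
    f$classes[which.max(post)]
  })
  expect_identical(predictScore(m, d), as.integer(oracle))

  # independent reference fit: MASS::lda agrees on this well-posed problem
  ref <- MASS::lda(fs ~ f1 + f2, data = d)
  expect_identical(predictScore(m, d),
                   as.integer(as.character(predict(ref, d)$class)))
})

test_that("LDA survives a degenerate class via ridge regularization", {
  d <- makeGaussianData(60, matrix(c(0, 5), 2, 1), sdev = 0.5, seed = 23)
  d$f2 <- 1  # constant column: singular pooled covariance
  expect_warning(m <- trainLdaScorer(d, c("f1", "f2")), "ridge")
  expect_true(all(predictScore(m, d) %in% 1:2))
})

test_that("SVM grid search selects by lowest CV RMSE with tie-breaking", {
  # noiseless, nearly linear relation: an easy regression
  set.seed(31)
  d <- data.frame(fs = sample(1:9, 300, replace = TRUE))
  d$f1 <- d$fs + runif(300, -0.05, 0.05)   # score = round(feature)
  m <- trainSvmScorer(d, "f1", folds = 5L, seed = 3)
  expect_lt(min(m@cvTable$rmse), 0.2)
  expect_true(mean(predictScore(m, d) == d$fs) > 0.95)

  # degenerate grid of one pair is selected verbatim
  m1 <- trainSvmScorer(d, "f1", costGrid = 4, epsilonGrid = 0.3,
                       folds = 3L, seed = 3)
  expect_identical(m1@hyper$cost, 4)
  expect_identical(m1@hyper$epsilon, 0.3)

  dConst <- d; dConst$fs <- 5L
  expect_error(trainSvmScorer(dConst, "f1", folds = 3L), "constant")
})

test_that("CV RMSE grid matches an independent fold-by-fold tabulation", {
  set.seed(32)
  d <- data.frame(f1 = rnorm(20), f2 = rnorm(20),
                  fs = rep(c(2L, 7L), each = 10))
  costs <- c(1, 10); eps <- c(0.1, 0.5)
  m <- trainSvmScorer(d, c("f1", "f2"), costGrid = costs,
                      epsilonGrid = eps, folds = 2L, seed = 5)
  # same fold assignment, independently scripted CV loop
  fold <- idcscore:::assignFolds(d$fs, 2L, 5L)
  X <- scale(as.matrix(d[, c("f1", "f2")]))
  for (cc in costs) for (ee in eps) {
    errs <- numeric(0)
    for (f in 1:2) {
      fit <- e1071::svm(X[fold != f, ], as.numeric(d$fs[fold != f]),
                        type = "eps-regression", kernel = "radial",
                        gamma = 0.5, cost = cc, epsilon = ee, scale = FALSE)
      errs <- c(errs, predict(fit, X[fold == f, , drop = FALSE]) -
                  d$fs[fold == f])
    }
    want <- sqrt(mean(errs^2))
    got <- m@cvTable$rmse[m@cvTable$cost == cc & m@cvTable$epsilon == ee]
    expect_equal(got, want, tolerance = 1e-10)
  }
  best <- m@cvTable[order(m@cvTable$rmse, m@cvTable$cost,
                          m@cvTable$epsilon), ][1, ]
  expect_identical(m@hyper$cost, best$cost)
  expect_identical(m@hyper$epsilon, best$epsilon)
})

test_that("SVM raw output is rounded half-up and clipped to 1..9", {
  raws <- c(3.49, 3.5, 12.2, -1, 0.2, 8.51)
  fake <- structure(list(), class = "fakeFit")
  registerS3method("predict", "fakeFit",
                   function(object, newdata, ...) newdata[, 1])
  m <- new("IdcScorer", method = "SVM", featureNames = "f1", fit = fake,
           center = c(f1 = 0), scale = c(f1 = 1), cvTable = data.frame(),
           hyper = list())
  expect_identical(predictScore(m, data.frame(f1 = raws)),
                   c(3L, 4L, 9L, 1L, 1L, 9L))
  expect_error(predictScore(m, data.frame(x = 1)), "missing feature")
})

test_that("confusion tallies and accuracies match their definitions", {
  cm <- confusionMatrix9(1:9, 1:9)
  expect_identical(cm@counts, matrix(as.integer(diag(9)), 9, 9,
                                     dimnames = dimnames(cm@counts)))
  expect_identical(accuracyI(cm), 100)
  expect_identical(accuracyII(cm), 100)

  set.seed(33)
  for (rep in 1:10) {
    p <- sample(1:9, 200, replace = TRUE)
    r <- sample(1:9, 200, replace = TRUE)
    cm <- confusionMatrix9(p, r)
    expect_identical(unname(cm@counts), oracleConfusion(p, r))
    expect_identical(sum(cm@counts), 200L)
    expect_gte(accuracyII(cm), accuracyI(cm))
    expect_lte(accuracyII(cm), 100)
  }
  expect_error(confusionMatrix9(1:3, 1:4))
  expect_error(confusionMatrix9(c(0, 1), c(1, 1)))
  expect_error(accuracyI(new("ConfusionMatrix9",
                             counts = matrix(0L, 9, 9))))
})
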