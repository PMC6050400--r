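#' Default model feature set
#'
#' The five features used by the scoring models by default: canopy-cover
#' fraction plus the four IDC-responsive hue-class fractions. `ratio_gc`
#' is extracted and reported but excluded from modelling because it is
#' insensitive to IDC severity; `ppc` duplicates `ppcf` up to the image
#' area and can be added via `includePpc`.
#'
#' @param includePpc also include the raw plant pixel count.
#' @param includeRatioGc also include the Green-Cyan fraction.
#' @return Character vector of feature column names.
#' @export
defaultFeatureSet <- function(includePpc = FALSE, includeRatioGc = FALSE) {
  fs <- c("ppcf", "ratio_g", "ratio_yg", "ratio_y", "ratio_oy")
  if (includeRatioGc) fs <- c(fs, "ratio_gc")
  if (includePpc) fs <- c("ppc", fs)
  fs
}

checkScoredData <- function(data, featureNames, refCol) {
  if (!is.data.frame(data)) stop("data must be a data.frame")
  miss <- setdiff(c(featureNames, refCol), names(data))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  if (anyNA(data[, c(featureNames, refCol)]))
    stop("missing values in features or reference scores")
  y <- data[[refCol]]
  if (!all(y == as.integer(y)) || any(y < 1 | y > 9))
    stop("reference scores must be integers in 1..9")
  invisible(TRUE)
}

#' Split a scored dataset randomly and equally into training and test sets
#'
#' Seeded random half/half split; for odd `n` the extra row goes to the
#' training set. The same seed always yields the same partition.
#'
#' @param data data.frame of scored plots.
#' @param seed integer RNG seed.
#' @return List with `train` and `test` data.frames (disjoint, union =
#'   input).
#' @export
splitTrainTest <- function(data, seed = 1L) {
  if (!is.data.frame(data) || nrow(data) < 2L)
    stop("need at least 2 rows to split")
  n <- nrow(data)
  idx <- withSeed(seed, sample.int(n))
  nTrain <- (n + 1L) %/% 2L
  list(train = data[sort(idx[seq_len(nTrain)]), , drop = FALSE],
       test = data[sort(idx[(nTrain + 1L):n]), , drop = FALSE])
}

#' Train a Gaussian LDA computer-scoring model
#'
#' Linear discriminant analysis with per-class means, a pooled
#' within-class covariance and empirical class priors; prediction is the
#' arg-max posterior over the score classes present in training. When the
#' pooled covariance is near-singular it is ridge-regularized by
#' `lambda = 1e-6 * trace / p` on the diagonal (with a warning), so small
#' or degenerate classes do not abort the pipeline.
#'
#' @param train data.frame of training plots.
#' @param featureNames feature columns (default [defaultFeatureSet()]).
#' @param refCol reference score column, `"fs"` (field score) or `"os"`
#'   (office score).
#' @return An [IdcScorer-class] with `method = "LDA"`.
#' @export
trainLdaScorer <- function(train, featureNames = defaultFeatureSet(),
                           refCol = "fs") {
  checkScoredData(train, featureNames, refCol)
  X <- as.matrix(train[, featureNames, drop = FALSE])
  y <- as.integer(train[[refCol]])
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("training data contains a single class")
  p <- ncol(X)
  means <- do.call(rbind, lapply(classes, function(k)
    colMeans(X[y == k, , drop = FALSE])))
  centered <- X - means[match(y, classes), , drop = FALSE]
  pooled <- crossprod(centered) / (nrow(X) - length(classes))
  lambda <- 0
  if (rcond(pooled) < 1e-10) {
    lambda <- 1e-6 * sum(diag(pooled)) / p
    if (lambda <= 0) lambda <- 1e-12
    pooled <- pooled + diag(lambda, p)
    warning("pooled covariance near-singular; ridge-regularized with lambda = ",
            signif(lambda, 3))
  }
  covInv <- solve(pooled)
  priors <- as.numeric(table(factor(y, levels = classes))) / length(y)
  new("IdcScorer", method = "LDA", featureNames = featureNames,
      fit = list(classes = classes, means = means, covInv = covInv,
                 logPriors = log(priors), lambda = lambda),
      center = numeric(0), scale = numeric(0),
      cvTable = data.frame(), hyper = list())
}

# stratified fold assignment: shuffle within each score class
assignFolds <- function(y, folds, seed) {
  withSeed(seed, {
    fold <- integer(length(y))
    for (k in unique(y)) {
      i <- which(y == k)
      fold[i] <- sample(rep_len(seq_len(folds), length(i)))
    }
    fold
  })
}

#' Train an RBF support-vector-regression scoring model with grid search
#'
#' The 1-9 score is treated as numeric and fitted with
#' epsilon-insensitive support-vector regression (radial-basis-function
#' kernel). Cost and epsilon are chosen by seeded stratified k-fold
#' cross-validation: for every grid pair the RMSE of the raw (unrounded)
#' held-out predictions is pooled over folds, and the pair with the
#' lowest RMSE wins (ties broken by smaller cost, then smaller epsilon).
#' The winning pair is refit on all training rows. Features are
#' standardized to zero mean / unit variance using training statistics.
#'
#' @param train data.frame of training plots.
#' @param featureNames feature columns (default [defaultFeatureSet()]).
#' @param refCol reference score column (`"fs"` or `"os"`).
#' @param costGrid candidate costs (default `2^(-1:7)`).
#' @param epsilonGrid candidate epsilons (default
#'   `c(0.05, 0.1, 0.2, 0.4, 0.8)`).
#' @param folds number of CV folds (default 10).
#' @param gamma RBF kernel width; default `1 / length(featureNames)`.
#' @param seed integer seed for the fold assignment.
#' @return An [IdcScorer-class] with `method = "SVM"`; slot `cvTable`
#'   holds the full CV grid.
#' @export
trainSvmScorer <- function(train, featureNames = defaultFeatureSet(),
                           refCol = "fs", costGrid = 2^(-1:7),
                           epsilonGrid = c(0.05, 0.1, 0.2, 0.4, 0.8),
                           folds = 10L, gamma = NULL, seed = 1L) {
  checkScoredData(train, featureNames, refCol)
  if (!length(costGrid) || !length(epsilonGrid)) stop("empty tuning grid")
  if (folds < 2L) stop("folds must be >= 2")
  if (nrow(train) < folds) stop("need at least `folds` training rows")
  y <- as.numeric(train[[refCol]])
  if (length(unique(y)) < 2L) stop("constant reference score")
  X <- as.matrix(train[, featureNames, drop = FALSE])
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, ctr, scl)
  if (is.null(gamma)) gamma <- 1 / length(featureNames)

  fold <- assignFolds(as.integer(y), as.integer(folds), seed)
  grid <- expand.grid(cost = costGrid, epsilon = epsilonGrid)
  grid$rmse <- NA_real_
  for (g in seq_len(nrow(grid))) {
    se <- 0
    for (f in seq_len(folds)) {
      hold <- fold == f
      fit <- e1071::svm(Xs[!hold, , drop = FALSE], y[!hold],
                        type = "eps-regression", kernel = "radial",
                        gamma = gamma, cost = grid$cost[g],
                        epsilon = grid$epsilon[g], scale = FALSE)
      pred <- stats::predict(fit, Xs[hold, , drop = FALSE])
      se <- se + sum((pred - y[hold])^2)
    }
    grid$rmse[g] <- sqrt(se / length(y))
  }
  best <- grid[order(grid$rmse, grid$cost, grid$epsilon), ][1, ]
  fit <- e1071::svm(Xs, y, type = "eps-regression", kernel = "radial",
                    gamma = gamma, cost = best$cost, epsilon = best$epsilon,
                    scale = FALSE)
  new("IdcScorer", method = "SVM", featureNames = featureNames,
      fit = fit, center = ctr, scale = scl, cvTable = grid,
      hyper = list(cost = best$cost, epsilon = best$epsilon, gamma = gamma,
                   folds = as.integer(folds), seed = as.integer(seed)))
}

#' Predict integer IDC scores
#'
#' LDA models return the arg-max posterior class. SVM models return the
#' raw regression output rounded half-up to the nearest integer and
#' clipped to `[1, 9]`.
#'
#' @param model an [IdcScorer-class].
#' @param newdata data.frame containing the model's feature columns.
#' @return Integer vector of scores in `{1..9}`.
#' @export
predictScore <- function(model, newdata) {
  stopifnot(is(model, "IdcScorer"))
  miss <- setdiff(model@featureNames, names(newdata))
  if (length(miss))
    stop("missing feature columns: ", paste(miss, collapse = ", "))
  X <- as.matrix(newdata[, model@featureNames, drop = FALSE])
  if (anyNA(X)) stop("missing feature values")
  if (model@method == "LDA") {
    f <- model@fit
    # discriminant: x' S^-1 mu_k - mu_k' S^-1 mu_k / 2 + log pi_k
    lin <- X %*% f$covInv %*% t(f$means)
    const <- -0.5 * rowSums((f$means %*% f$covInv) * f$means) + f$logPriors
    disc <- sweep(lin, 2, const, "+")
    as.integer(f$classes[max.col(disc, ties.method = "first")])
  } else {
    Xs <- scale(X, model@center, model@scale)
    raw <- as.numeric(stats::predict(model@fit, Xs))
    as.integer(pmin(9, pmax(1, roundHalfUp(raw))))
  }
}

#' Tally a 9 x 9 confusion matrix
#'
#' @param predicted integer computer scores in `{1..9}` (rows).
#' @param reference integer reference scores in `{1..9}` (columns).
#' @return A [ConfusionMatrix9-class].
#' @export
confusionMatrix9 <- function(predicted, reference) {
  if (length(predicted) != length(reference))
    stop("predicted and reference must have equal length")
  if (!all(predicted %in% 1:9) || !all(reference %in% 1:9))
    stop("scores must be integers in 1..9")
  counts <- table(factor(predicted, levels = 1:9),
                  factor(reference, levels = 1:9))
  m <- matrix(as.integer(counts), 9, 9,
              dimnames = list(computer = 1:9, reference = 1:9))
  new("ConfusionMatrix9", counts = m)
}

#' Exact-match accuracy (Accuracy I)
#'
#' `100 * sum(diagonal) / n`: the percentage of plots whose computer
#' score equals the reference score on the 9-point scale.
#'
#' @param cm a [ConfusionMatrix9-class].
#' @return Percentage in `[0, 100]`.
#' @export
accuracyI <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix9"))
  n <- sum(cm@counts)
  if (n == 0) stop("empty confusion matrix")
  100 * sum(diag(cm@counts)) / n
}

#' Within-one-point accuracy (Accuracy II)
#'
#' `100 * sum(cells with |row - col| <= 1) / n`: predictions off by at
#' most one point count as correct, reflecting the coarser 5-point scale
#' also in common use for IDC.
#'
#' @param cm a [ConfusionMatrix9-class].
#' @return Percentage in `[0, 100]`; always `>= accuracyI(cm)`.
#' @export
accuracyII <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix9"))
  n <- sum(cm@counts)
  if (n == 0) stop("empty confusion matrix")
  near <- abs(row(cm@counts) - col(cm@counts)) <= 1
  100 * sum(cm@counts[near]) / n
}

#' Evaluate a trained scorer on a test set
#'
#' @param model an [IdcScorer-class].
#' @param test data.frame with the model's features and the reference
#'   column.
#' @param refCol reference score column.
#' @return A [ConfusionMatrix9-class].
#' @export
evaluateScorer <- function(model, test, refCol = "fs") {
  if (!nrow(test)) stop("empty test set")
  checkScoredData(test, model@featureNames, refCol)
  confusionMatrix9(predictScore(model, test), as.integer(test[[refCol]]))
}
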