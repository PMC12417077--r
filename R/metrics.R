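## Multi-class evaluation metrics and downstream classifiers.
##
## The multi-class MCC is computed from totals over the confusion
## matrix: with n instances, p correct, n_c the occurrences and p_c the
## predictions of class c,
##   MCC = (n p - sum_c n_c p_c) /
##         sqrt((n^2 - sum_c p_c^2) (n^2 - sum_c n_c^2)),
## defined as 0 when either factor under the root vanishes. Macro-F1
## averages per-class F1 = 2TP / (2TP + FP + FN) over the full class
## alphabet (a class absent from both vectors contributes 0).

asPredictionSet <- function(x, yPred = NULL, classAlphabet = NULL) {
  if (methods::is(x, "PredictionSet")) return(x)
  PredictionSet(x, yPred, classAlphabet)
}

classCounts <- function(ps) {
  C <- ps@classAlphabet
  list(
    n = length(ps@yTrue),
    p = sum(ps@yTrue == ps@yPred),
    nc = vapply(C, function(c) sum(ps@yTrue == c), numeric(1)),
    pc = vapply(C, function(c) sum(ps@yPred == c), numeric(1)))
}

#' Multi-class Matthews correlation coefficient
#'
#' @param x a [PredictionSet-class], or the true-label vector.
#' @param yPred predicted labels (when `x` is a vector).
#' @param classAlphabet optional ordered label set.
#' @return MCC in \[-1, 1\]; 0 when a denominator factor is 0 (e.g. all
#'   predictions in one class).
#' @examples
#' mccScore(c("A", "A", "B"), c("A", "B", "B"))
#' @export
mccScore <- function(x, yPred = NULL, classAlphabet = NULL) {
  ps <- asPredictionSet(x, yPred, classAlphabet)
  k <- classCounts(ps)
  d1 <- k$n^2 - sum(k$pc^2)
  d2 <- k$n^2 - sum(k$nc^2)
  if (d1 <= 0 || d2 <= 0) return(0)
  (k$n * k$p - sum(k$nc * k$pc)) / sqrt(d1 * d2)
}

#' Macro-averaged F1 score
#'
#' @inheritParams mccScore
#' @return unweighted mean of per-class F1 over the class alphabet, in
#'   \[0, 1\].
#' @export
f1Macro <- function(x, yPred = NULL, classAlphabet = NULL) {
  ps <- asPredictionSet(x, yPred, classAlphabet)
  f1 <- vapply(ps@classAlphabet, function(c) {
    tp <- sum(ps@yTrue == c & ps@yPred == c)
    fp <- sum(ps@yTrue != c & ps@yPred == c)
    fn <- sum(ps@yTrue == c & ps@yPred != c)
    den <- 2 * tp + fp + fn
    if (den == 0) 0 else 2 * tp / den
  }, numeric(1))
  mean(f1)
}

#' Classification accuracy
#'
#' @inheritParams mccScore
#' @return fraction of correctly predicted instances.
#' @export
accuracyScore <- function(x, yPred = NULL, classAlphabet = NULL) {
  ps <- asPredictionSet(x, yPred, classAlphabet)
  mean(ps@yTrue == ps@yPred)
}

# ---- downstream classifiers ------------------------------------------

#' Default SVM hyperparameter grid
#'
#' Linear and RBF kernels, cost in \{0.1, 1, 10, 100\}, gamma in
#' \{"scale" (1 / (d * var(X))), 0.01, 0.001\} for the RBF kernel.
#'
#' @return data.frame with columns `kernel`, `cost`, `gamma` (`NA` gamma
#'   means "scale").
#' @export
defaultSvmGrid <- function() {
  rbind(
    expand.grid(kernel = "linear", cost = c(0.1, 1, 10, 100), gamma = NA,
                stringsAsFactors = FALSE),
    expand.grid(kernel = "radial", cost = c(0.1, 1, 10, 100),
                gamma = c(NA, 0.01, 0.001), stringsAsFactors = FALSE))
}

# A compact grid used inside the training loop, where the SVM is refit
# at every selection checkpoint.
selectionSvmGrid <- function() {
  expand.grid(kernel = c("linear", "radial"), cost = c(1, 10), gamma = NA,
              stringsAsFactors = FALSE)
}

resolveGamma <- function(gamma, X) {
  if (is.na(gamma)) {
    v <- stats::var(as.vector(X))
    if (v <= 0) v <- 1
    1 / (ncol(X) * v)
  } else gamma
}

fitSvm <- function(X, y, row) {
  if (row$kernel == "linear")
    e1071::svm(X, factor(y), kernel = "linear", cost = row$cost,
               scale = FALSE)
  else
    e1071::svm(X, factor(y), kernel = "radial", cost = row$cost,
               gamma = resolveGamma(row$gamma, X), scale = FALSE)
}

# Stratified inner-CV grid search selecting by MCC, then refit on all
# training data. Deterministic given seed. Ties go to the earlier grid
# row.
svmGridSearch <- function(X, y, grid = defaultSvmGrid(), seed = 1L,
                          innerFolds = 3L) {
  y <- as.character(y)
  folds <- integer(length(y))
  withSeed(deriveSeed(seed, 3L), {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- ((seq_along(idx) - 1L) %% innerFolds) + 1L
    }
  })
  scores <- vapply(seq_len(nrow(grid)), function(g) {
    mean(vapply(seq_len(innerFolds), function(f) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2L || !any(!tr)) return(NA_real_)
      fit <- fitSvm(X[tr, , drop = FALSE], y[tr], grid[g, ])
      mccScore(y[!tr],
               as.character(predict(fit, X[!tr, , drop = FALSE])))
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  best <- which.max(scores)
  list(model = fitSvm(X, y, grid[best, ]), grid = grid[best, ],
       score = scores[best])
}

#' Fit a downstream classifier on representations and predict
#'
#' Scores a feature representation with one of the three downstream
#' classifiers: an SVM with inner stratified 3-fold grid search selected
#' by MCC and refit on all training data, a random forest with fixed
#' defaults, or k-nearest neighbours.
#'
#' @param trainX,trainY training representations (rows = cells) and
#'   labels; at least two classes.
#' @param testX representations to predict.
#' @param testY optional ground-truth labels for `testX`.
#' @param kind `"svm"`, `"rf"` or `"knn"`.
#' @param grid SVM hyperparameter grid (see [defaultSvmGrid()]); for
#'   knn a list with element `k` (default 5; `k = 1` memorises).
#' @param seed integer seed (grid-search folds, forest randomness, knn
#'   tie-breaks).
#' @return a [PredictionSet-class] pairing `testY` (when supplied) with
#'   the predictions; without `testY` the truth slot repeats the
#'   predictions and only the predictions are meaningful.
#' @export
fitPredictClassifier <- function(trainX, trainY, testX, testY = NULL,
                                 kind = c("svm", "rf", "knn"),
                                 grid = NULL, seed = 1L) {
  kind <- match.arg(kind)
  trainY <- as.character(trainY)
  if (length(unique(trainY)) < 2L)
    stopf("training data must contain at least two classes")
  if (ncol(trainX) != ncol(testX))
    stopf("train and test have different feature counts")
  pred <- switch(kind,
    svm = {
      if (is.null(grid)) grid <- defaultSvmGrid()
      fit <- svmGridSearch(trainX, trainY, grid, seed)
      as.character(predict(fit$model, testX))
    },
    rf = withSeed(deriveSeed(seed, 4L), {
      fit <- randomForest::randomForest(trainX, factor(trainY))
      as.character(predict(fit, testX))
    }),
    knn = withSeed(deriveSeed(seed, 5L), {
      k <- if (is.list(grid) && !is.null(grid$k)) grid$k else 5L
      as.character(class::knn(trainX, testX, factor(trainY), k = k))
    }))
  alphabet <- sort(unique(c(trainY, pred,
                            if (!is.null(testY)) as.character(testY))))
  PredictionSet(if (is.null(testY)) pred else as.character(testY),
                pred, alphabet)
}
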