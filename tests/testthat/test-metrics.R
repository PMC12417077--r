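test_that("metrics reproduce hand-computed values on the worked example", {
  yt <- c("A", "A", "A", "B", "B", "C")
  yp <- c("A", "B", "A", "B", "B", "C")
  # counts: n=6, p=5, nc=(3,2,1), pc=(2,3,1)
  expect_equal(mccScore(yt, yp), (6 * 5 - 13) / sqrt((36 - 14) * (36 - 14)),
               tolerance = 1e-15)
  # per-class F1: A 4/5, B 4/5, C 1
  expect_equal(f1Macro(yt, yp), mean(c(4 / 5, 4 / 5, 1)),
               tolerance = 1e-15)
  expect_equal(accuracyScore(yt, yp), 5 / 6, tolerance = 1e-15)
})

test_that("perfect, degenerate and empty-class conventions hold", {
  y <- c("A", "B", "A", "C")
  expect_equal(mccScore(y, y), 1)
  expect_equal(f1Macro(y, y), 1)
  expect_equal(accuracyScore(y, y), 1)
  # all predictions one class over a 2-class truth -> MCC 0 by convention
  expect_equal(mccScore(c("A", "A", "B", "B"), rep("A", 4)), 0)
  # an alphabet class absent from both vectors contributes F1 = 0
  expect_equal(f1Macro(c("A", "A"), c("A", "A"),
                       classAlphabet = c("A", "B")), 0.5)
  # zero matches
  expect_equal(accuracyScore(c("A", "B"), c("B", "A")), 0)
})

test_that("metrics agree with the confusion-matrix oracle on random sets", {
  set.seed(2024)
  for (k in 1:200) {
    K <- sample(2:13, 1)
    n <- sample(5:500, 1)
    C <- paste0("c", seq_len(K))
    yt <- sample(C, n, replace = TRUE)
    yp <- sample(C, n, replace = TRUE)
    o <- oracleMetrics(yt, yp, C)
    expect_equal(mccScore(yt, yp, classAlphabet = C), o$mcc,
                 tolerance = 1e-12)
    expect_equal(f1Macro(yt, yp, classAlphabet = C), o$f1,
                 tolerance = 1e-12)
    expect_equal(accuracyScore(yt, yp, classAlphabet = C), o$acc,
                 tolerance = 1e-12)
    expect_gte(o$mcc, -1); expect_lte(mccScore(yt, yp), 1)
    expect_gte(o$f1, 0); expect_lte(o$f1, 1)
  }
})

test_that("metrics are equivariant under consistent class relabelling", {
  set.seed(11)
  C <- LETTERS[1:5]
  yt <- sample(C, 120, replace = TRUE)
  yp <- sample(C, 120, replace = TRUE)
  perm <- setNames(sample(C), C)
  expect_equal(mccScore(perm[yt], perm[yp]), mccScore(yt, yp),
               tolerance = 1e-12)
  expect_equal(f1Macro(perm[yt], perm[yp]), f1Macro(yt, yp),
               tolerance = 1e-12)
  expect_equal(accuracyScore(perm[yt], perm[yp]), accuracyScore(yt, yp))
})

test_that("all three classifiers solve separable blobs", {
  set.seed(3)
  n <- 60
  trX <- rbind(matrix(rnorm(n, 0, 0.3), n / 2, 2),
               matrix(rnorm(n, 5, 0.3), n / 2, 2))
  trY <- rep(c("A", "B"), each = n / 2)
  teX <- rbind(matrix(rnorm(20, 0, 0.3), 10, 2),
               matrix(rnorm(20, 5, 0.3), 10, 2))
  teY <- rep(c("A", "B"), each = 10)
  for (kind in c("svm", "rf", "knn")) {
    ps <- fitPredictClassifier(trX, trY, teX, teY, kind = kind, seed = 1)
    expect_equal(mccScore(ps), 1, info = kind)
  }
})

test_that("memorising knn reproduces its training labels", {
  set.seed(4)
  X <- matrix(rnorm(80), 40, 2)
  y <- sample(c("A", "B", "C"), 40, replace = TRUE)
  ps <- fitPredictClassifier(X, y, X, y, kind = "knn",
                             grid = list(k = 1), seed = 1)
  expect_equal(accuracyScore(ps), 1)
})

test_that("the SVM grid search is deterministic given a seed", {
  set.seed(5)
  X <- matrix(rnorm(200 * 4), 200, 4)
  y <- ifelse(X[, 1] + 0.5 * rnorm(200) > 0, "A", "B")
  r1 <- scAFCL:::svmGridSearch(X, y, defaultSvmGrid(), seed = 6)
  r2 <- scAFCL:::svmGridSearch(X, y, defaultSvmGrid(), seed = 6)
  expect_identical(r1$grid, r2$grid)
  teX <- matrix(rnorm(40), 10, 4)
  expect_identical(as.character(predict(r1$model, teX)),
                   as.character(predict(r2$model, teX)))
  expect_error(fitPredictClassifier(X, rep("A", 200), X, kind = "svm"),
               "two classes")
})
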