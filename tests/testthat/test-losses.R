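test_that("cosine similarity matches scalar arithmetic and handles edge cases", {
  expect_equal(cosineSimilarity(c(2, 3, -1), c(2, 3, -1)), 1)
  expect_equal(cosineSimilarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosineSimilarity(c(3, 4), c(4, 3)),
               (3 * 4 + 4 * 3) / (5 * 5), tolerance = 1e-12)
  expect_error(cosineSimilarity(c(0, 0), c(1, 1)), "zero vector")
})

test_that("anchor context partitions the batch around the anchor", {
  lab <- c("A", "B", "A", "C", "A")
  ctx <- anchorContext(lab, 1)
  expect_setequal(ctx$positives, c(3, 5))
  expect_setequal(ctx$negatives, c(2, 4))
  expect_false(1 %in% c(ctx$positives, ctx$negatives))
  expect_setequal(c(1, ctx$positives, ctx$negatives), 1:5)
})

test_that("anchor losses reproduce the hand-evaluated closed forms", {
  # no negatives -> every fraction is 1 -> loss exactly 0
  expect_equal(afclAnchorLoss(rbind(c(1, 0), c(2, 0), c(0.5, 0)),
                              c("A", "A", "A"), 1, 0.1), 0)
  # one positive at similarity 1, one negative at similarity 0, tau 0.1:
  # -log(e^10 / (e^10 + 1)) = log(1 + e^-10)
  H <- rbind(c(1, 0), c(1, 0), c(0, 1))
  expect_equal(afclAnchorLoss(H, c("A", "A", "B"), 1, 0.1),
               log(1 + exp(-10)), tolerance = 1e-12)
  # two identical positives, no negatives, supcon: log 2 per term
  expect_equal(supconAnchorLoss(matrix(1, 3, 2), c("A", "A", "A"), 1, 0.7),
               log(2), tolerance = 1e-12)
  # single positive: the two variants coincide exactly
  b <- randomBatch(6, 4, 6, seed = 31)
  b$lab <- c("A", "A", "B", "C", "D", "E")
  expect_equal(afclAnchorLoss(b$H, b$lab, 1, 0.1),
               supconAnchorLoss(b$H, b$lab, 1, 0.1), tolerance = 1e-14)
  expect_error(afclAnchorLoss(H, c("A", "B", "C"), 1, 0.1), "no in-batch")
})

test_that("vectorised losses match the double-loop oracle on random batches", {
  for (k in 1:25) {
    b <- randomBatch(m = sample(4:20, 1), d = sample(2:8, 1),
                     nClasses = sample(2:6, 1), seed = 100 + k)
    tau <- sample(c(0.05, 0.1, 0.5, 1), 1)
    for (v in c("afrcl", "supcon")) {
      expect_equal(batchLoss(b$H, b$lab, tau, v)$value,
                   oracleBatchLoss(b$H, b$lab, tau, v),
                   tolerance = 1e-6)
      i <- which(table(b$lab)[b$lab] >= 2)[1]
      fn <- if (v == "afrcl") afclAnchorLoss else supconAnchorLoss
      expect_equal(fn(b$H, b$lab, i, tau),
                   oracleAnchorLoss(b$H, b$lab, i, tau, v),
                   tolerance = 1e-6)
    }
  }
})

test_that("restricted loss never exceeds the conventional loss", {
  for (k in 1:40) {
    b <- randomBatch(m = sample(4:16, 1), d = 5,
                     nClasses = sample(2:5, 1), seed = 300 + k)
    for (i in seq_len(nrow(b$H))) {
      nPos <- sum(b$lab == b$lab[i]) - 1
      if (nPos == 0) next
      la <- afclAnchorLoss(b$H, b$lab, i, 0.1)
      ls <- supconAnchorLoss(b$H, b$lab, i, 0.1)
      expect_gte(la, 0)
      expect_lte(la, ls + 1e-12)
      if (nPos == 1) expect_equal(la, ls, tolerance = 1e-12)
      else expect_lt(la, ls)
    }
  }
})

test_that("losses are invariant to projection scale and cell order", {
  b <- randomBatch(10, 6, 3, seed = 77)
  scale <- diag(runif(10, 0.1, 9))
  for (v in c("afrcl", "supcon")) {
    l0 <- batchLoss(b$H, b$lab, 0.1, v)$value
    expect_equal(batchLoss(scale %*% b$H, b$lab, 0.1, v)$value, l0,
                 tolerance = 1e-9)
    perm <- sample(10)
    expect_equal(batchLoss(b$H[perm, ], b$lab[perm], 0.1, v)$value, l0,
                 tolerance = 1e-9)
  }
})

test_that("degenerate batches return zero with a warning", {
  H <- matrix(rnorm(8), 4, 2)
  expect_warning(res <- batchLoss(H, c("A", "B", "C", "D"), 0.1, "afrcl"),
                 "no anchor")
  expect_equal(res$value, 0)
  expect_true(res$degenerate)
})

test_that("identical-projection batch [A,A,B,B] gives log 3 per anchor", {
  H <- matrix(rep(c(2, 1, 0), each = 4), 4, 3)
  res <- batchLoss(H, c("A", "A", "B", "B"), 0.1, "afrcl")
  expect_equal(res$value, log(3), tolerance = 1e-12)
})

test_that("the analytic batch gradient matches finite differences", {
  for (v in c("afrcl", "supcon")) {
    b <- randomBatch(7, 4, 3, seed = if (v == "afrcl") 11 else 12)
    lg <- batchLossGradient(b$H, b$lab, 0.1, v)
    expect_equal(lg$value, batchLoss(b$H, b$lab, 0.1, v)$value,
                 tolerance = 1e-12)
    eps <- 1e-6
    num <- b$H * 0
    for (i in seq_len(nrow(b$H))) for (j in seq_len(ncol(b$H))) {
      Hp <- b$H; Hp[i, j] <- Hp[i, j] + eps
      Hm <- b$H; Hm[i, j] <- Hm[i, j] - eps
      num[i, j] <- (batchLoss(Hp, b$lab, 0.1, v)$value -
                    batchLoss(Hm, b$lab, 0.1, v)$value) / (2 * eps)
    }
    expect_lt(max(abs(num - lg$grad)), 1e-4)
  }
})
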