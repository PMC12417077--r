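# Independent scalar/double-loop references the vectorised code is
# checked against. Deliberately naive: no shared code with R/.

oracleCos <- function(a, b)
  sum(a * b) / (sqrt(sum(a * a)) * sqrt(sum(b * b)))

oracleAnchorLoss <- function(H, lab, i, tau, variant) {
  pos <- setdiff(which(lab == lab[i]), i)
  neg <- which(lab != lab[i])
  stopifnot(length(pos) > 0)
  total <- 0
  for (q in pos) {
    num <- exp(oracleCos(H[i, ], H[q, ]) / tau)
    den <- if (variant == "afrcl") {
      d <- num
      for (l in neg) d <- d + exp(oracleCos(H[i, ], H[l, ]) / tau)
      d
    } else {
      d <- 0
      for (a in c(pos, neg)) d <- d + exp(oracleCos(H[i, ], H[a, ]) / tau)
      d
    }
    total <- total - log(num / den)
  }
  total / length(pos)
}

oracleBatchLoss <- function(H, lab, tau, variant) {
  total <- 0
  for (i in seq_len(nrow(H))) {
    if (sum(lab == lab[i]) < 2) next
    total <- total + oracleAnchorLoss(H, lab, i, tau, variant)
  }
  total / nrow(H)
}

# Confusion-matrix metric references.
oracleMetrics <- function(yt, yp, C = sort(unique(c(yt, yp)))) {
  cm <- table(factor(yt, levels = C), factor(yp, levels = C))
  n <- sum(cm)
  p <- sum(diag(cm))
  nc <- rowSums(cm)
  pc <- colSums(cm)
  d1 <- n^2 - sum(pc^2); d2 <- n^2 - sum(nc^2)
  mcc <- if (d1 <= 0 || d2 <= 0) 0 else
    (n * p - sum(nc * pc)) / sqrt(d1 * d2)
  f1 <- numeric(length(C))
  for (k in seq_along(C)) {
    tp <- cm[k, k]; fp <- sum(cm[, k]) - tp; fn <- sum(cm[k, ]) - tp
    f1[k] <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }
  list(mcc = mcc, f1 = mean(f1), acc = p / n)
}

oracleUniformity <- function(E, t) {
  Z <- E / sqrt(rowSums(E^2))
  vals <- c()
  for (i in seq_len(nrow(Z) - 1)) for (j in (i + 1):nrow(Z))
    vals <- c(vals, exp(-t * sum((Z[i, ] - Z[j, ])^2)))
  -log(mean(vals))
}

oracleTolerance <- function(E, lab) {
  vals <- c()
  for (i in seq_len(nrow(E) - 1)) for (j in (i + 1):nrow(E))
    if (lab[i] == lab[j]) vals <- c(vals, oracleCos(E[i, ], E[j, ]))
  mean(vals)
}

# Random projection batch guaranteed to contain repeated labels.
randomBatch <- function(m, d, nClasses, seed) {
  set.seed(seed)
  lab <- sample(LETTERS[seq_len(nClasses)], m, replace = TRUE)
  lab[2] <- lab[1]   # at least one anchor with a positive
  list(H = matrix(rnorm(m * d), m, d), lab = lab)
}

# Small labelled dataset for training-level tests.
tinyTrainingData <- function(nCells = 200, nGenes = 100, nTypes = 3,
                             shift = 2.5, seed = 3L) {
  simulateCells(SyntheticConfig(nCells = nCells, nGenes = nGenes,
                                nTypes = nTypes, signatureSize = 10L,
                                logFoldShift = shift, seed = seed))
}

tinySpec <- function(nGenes = 100)
  NetworkSpec(nGenes, encoderHidden = c(64L, 64L),
              representationDim = 32L, projectorHidden = 16L,
              projectionDim = 8L)
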