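test_that("dense TSV round-trip preserves entries, names and labels", {
  mat <- matrix(0, 3, 2)
  sce <- newCellDataset(mat, c("g1", "g2"), c("c1", "c2", "c3"),
                        c("A", "A", "B"))
  prefix <- file.path(withr::local_tempdir(), "zero_")
  p <- writeCellDataset(sce, prefix, "dense_tsv")
  back <- readCellDataset(p$matrix, p$labels, "dense_tsv")
  expect_identical(unname(cellMatrix(back)), mat)
  expect_false(isLogTransformed(back))
  expect_identical(cellTypes(back), c("A", "A", "B"))

  set.seed(1)
  mat2 <- matrix(rpois(12, 2), 4, 3)
  sce2 <- newCellDataset(mat2, paste0("g", 1:3), paste0("c", 1:4),
                         c("A", "B", "A", "B"))
  p2 <- writeCellDataset(sce2, file.path(withr::local_tempdir(), "x_"),
                         "dense_tsv")
  back2 <- readCellDataset(p2$matrix, p2$labels, "dense_tsv")
  expect_equal(unname(cellMatrix(back2)), mat2)
  expect_identical(colnames(cellMatrix(back2)), paste0("g", 1:3))
})

test_that("mtx round-trip places every nonzero at its stated coordinate", {
  # 4 cells x 6 genes with 5 hand-chosen nonzeros
  coords <- data.frame(cell = c(1L, 1L, 2L, 3L, 4L),
                       gene = c(2L, 5L, 1L, 6L, 3L),
                       value = c(3, 1, 7, 2, 5))
  mat <- matrix(0, 4, 6)
  mat[cbind(coords$cell, coords$gene)] <- coords$value
  sce <- newCellDataset(mat, paste0("g", 1:6), paste0("c", 1:4),
                        c("A", "A", "B", "B"))
  p <- writeCellDataset(sce, file.path(withr::local_tempdir(), "m_"),
                        "mtx")
  back <- readCellDataset(p$matrix, p$labels, "mtx",
                          genesPath = p$genes, barcodesPath = p$barcodes)
  dense <- cellMatrix(back)
  expect_equal(sum(dense != 0), 5)
  for (r in seq_len(nrow(coords)))
    expect_equal(dense[coords$cell[r], coords$gene[r]], coords$value[r])
  expect_equal(unname(dense), mat)
})

test_that("loader rejects missing labels, negatives, and dim mismatches", {
  sce <- newCellDataset(matrix(1, 3, 2), c("g1", "g2"),
                        c("c1", "c2", "c3"), c("A", "A", "B"))
  dir <- withr::local_tempdir()
  p <- writeCellDataset(sce, file.path(dir, "a_"), "dense_tsv")
  lab <- read.table(p$labels, sep = "\t")
  write.table(lab[-2, ], p$labels, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  expect_error(readCellDataset(p$matrix, p$labels), "c2")

  expect_error(newCellDataset(matrix(c(1, -2, 0, 0), 2, 2),
                              c("g1", "g2"), c("c1", "c2"), c("A", "B")),
               "cell 2, gene 1")

  pm <- writeCellDataset(sce, file.path(dir, "b_"), "mtx")
  writeLines(c("g1"), pm$genes)  # one gene name too few
  expect_error(readCellDataset(pm$matrix, pm$labels, "mtx",
                               genesPath = pm$genes,
                               barcodesPath = pm$barcodes),
               "gene names")
})

test_that("log transform is ln(1+x), flagged, and refuses to run twice", {
  set.seed(2)
  mat <- matrix(runif(9, 0, 5), 3, 3)
  mat[1, 1] <- 0
  mat[2, 2] <- exp(1) - 1
  sce <- newCellDataset(mat, paste0("g", 1:3), paste0("c", 1:3),
                        c("A", "B", "A"))
  out <- logTransform(sce)
  expect_true(isLogTransformed(out))
  got <- cellMatrix(out)
  # scalar-loop oracle
  for (i in 1:3) for (j in 1:3)
    expect_equal(got[i, j], log(1 + mat[i, j]), tolerance = 1e-12)
  expect_equal(got[1, 1], 0)
  expect_equal(got[2, 2], 1)
  expect_error(logTransform(out), "already")
})

test_that("stratified split preserves class proportions and partitions cells", {
  # exact divisibility: 100 cells, 50/50, fraction 0.2
  lab <- rep(c("A", "B"), each = 50)
  sp <- stratifiedSplit(lab, 0.2, 5, seed = 7)
  val <- validationIndices(sp)
  expect_length(val, 20)
  expect_equal(sum(lab[val] == "A"), 10)
  for (f in 1:5) {
    idx <- foldIndices(sp, f)
    expect_equal(sum(lab[idx] == "A"), 8)
    expect_equal(sum(lab[idx] == "B"), 8)
  }
  # partition
  all_idx <- sort(c(val, unlist(lapply(1:5, foldIndices, split = sp))))
  expect_identical(all_idx, 1:100)

  # 105 cells at 2:1 -> every split within one cell of 2:1
  lab2 <- c(rep("A", 70), rep("B", 35))
  sp2 <- stratifiedSplit(lab2, 0.2, 5, seed = 7)
  chunks <- c(list(validationIndices(sp2)),
              lapply(1:5, foldIndices, split = sp2))
  for (idx in chunks) {
    nA <- sum(lab2[idx] == "A"); nB <- sum(lab2[idx] == "B")
    expect_lte(abs(nA - 2 * nB), 2)  # +-1 cell in each class count
  }

  # determinism
  sp3 <- stratifiedSplit(lab2, 0.2, 5, seed = 7)
  expect_identical(sp2@validationIdx, sp3@validationIdx)
  expect_identical(sp2@foldAssignments, sp3@foldAssignments)

  # class too small
  expect_error(stratifiedSplit(c(rep("A", 20), rep("B", 3)), 0.2, 5, 1),
               "'B'")
})

test_that("batching chunks to m, drops singletons, and reshuffles by epoch", {
  lab <- rep(c("A", "B"), 65)
  b <- makeBatches(1:130, lab, 64, seed = 1, epoch = 1)
  expect_equal(vapply(b, function(x) length(x$indices), integer(1)),
               c(64L, 64L, 2L))
  b2 <- makeBatches(1:129, lab[1:129], 64, seed = 1, epoch = 1)
  expect_equal(vapply(b2, function(x) length(x$indices), integer(1)),
               c(64L, 64L))

  # determinism given (seed, epoch); reshuffle across epochs
  b3 <- makeBatches(1:130, lab, 64, seed = 1, epoch = 1)
  expect_identical(lapply(b, `[[`, "indices"), lapply(b3, `[[`, "indices"))
  b4 <- makeBatches(1:130, lab, 64, seed = 1, epoch = 2)
  expect_false(identical(b[[1]]$indices, b4[[1]]$indices))

  # each retained index appears exactly once per epoch
  for (ep in 1:3) {
    bs <- makeBatches(1:130, lab, 64, seed = 5, epoch = ep)
    expect_identical(sort(unlist(lapply(bs, `[[`, "indices"))), 1:130)
  }
  expect_error(makeBatches(1:10, lab[1:10], 1, 1, 1), ">= 2")
})
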