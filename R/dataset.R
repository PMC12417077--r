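## Expression-data containers, file I/O, log transform, splitting, batching.
##
## Labelled expression data live in a SingleCellExperiment (genes x cells,
## the Bioconductor convention) with the cell-type annotation in
## colData()$cellType and a logTransformed flag in metadata(). The
## training code consumes cells x genes matrices via cellMatrix().

#' Build a labelled cell dataset
#'
#' Wraps a cells-by-genes expression matrix and per-cell cell-type labels
#' into a [SingleCellExperiment::SingleCellExperiment] with assay
#' `"counts"`, `colData()$cellType`, and a `logTransformed` metadata flag.
#'
#' @param mat numeric matrix, cells in rows, genes in columns; all
#'   entries must be finite and non-negative.
#' @param geneNames character vector, one per column of `mat`.
#' @param cellIds character vector, one per row of `mat`.
#' @param labels per-cell cell-type labels (character or factor).
#' @return a `SingleCellExperiment`.
#' @examples
#' sce <- newCellDataset(matrix(0, 3, 2), c("g1", "g2"),
#'                       c("c1", "c2", "c3"), c("A", "A", "B"))
#' @export
newCellDataset <- function(mat, geneNames, cellIds, labels) {
  mat <- as.matrix(mat)
  if (nrow(mat) != length(cellIds) || nrow(mat) != length(labels))
    stopf("matrix has %d rows but %d cell ids and %d labels",
          nrow(mat), length(cellIds), length(labels))
  if (ncol(mat) != length(geneNames))
    stopf("matrix has %d columns but %d gene names", ncol(mat),
          length(geneNames))
  bad <- which(!is.finite(mat) | mat < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stopf("negative or non-finite entry at cell %d, gene %d",
          bad[1L, 1L], bad[1L, 2L])
  counts <- t(mat)
  dimnames(counts) <- list(as.character(geneNames), as.character(cellIds))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(cellType = as.character(labels),
                                   row.names = as.character(cellIds)))
  S4Vectors::metadata(sce)$logTransformed <- FALSE
  sce
}

#' Read a labelled expression dataset from disk
#'
#' Supports a dense TSV (header `cell_id` followed by gene names, one row
#' per cell) and Matrix Market sparse triplets (`.mtx`, genes x cells,
#' with one-name-per-line gene and barcode companion files). Labels are a
#' two-column headerless TSV of `(cell_id, cell_type)`.
#'
#' @param matrixPath path to the dense TSV or `.mtx` file.
#' @param labelsPath path to the labels TSV.
#' @param format `"dense_tsv"` or `"mtx"`.
#' @param genesPath,barcodesPath companion name files (mtx only).
#' @return a `SingleCellExperiment` (see [newCellDataset()]).
#' @export
readCellDataset <- function(matrixPath, labelsPath,
                            format = c("dense_tsv", "mtx"),
                            genesPath = NULL, barcodesPath = NULL) {
  format <- match.arg(format)
  for (p in c(matrixPath, labelsPath, genesPath, barcodesPath))
    if (!file.exists(p)) stopf("file not found: %s", p)
  if (format == "dense_tsv") {
    tab <- read.table(matrixPath, header = TRUE, sep = "\t",
                      check.names = FALSE, row.names = NULL,
                      stringsAsFactors = FALSE)
    cellIds <- as.character(tab[[1L]])
    geneNames <- colnames(tab)[-1L]
    mat <- as.matrix(tab[, -1L, drop = FALSE])
    storage.mode(mat) <- "double"
  } else {
    if (is.null(genesPath) || is.null(barcodesPath))
      stopf("mtx format needs genesPath and barcodesPath")
    m <- Matrix::readMM(matrixPath)
    geneNames <- readLines(genesPath)
    cellIds <- readLines(barcodesPath)
    if (nrow(m) != length(geneNames))
      stopf("mtx has %d rows but %d gene names", nrow(m), length(geneNames))
    if (ncol(m) != length(cellIds))
      stopf("mtx has %d columns but %d barcodes", ncol(m), length(cellIds))
    mat <- t(as.matrix(m))  # stored genes x cells; present cells x genes
  }
  lab <- read.table(labelsPath, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (ncol(lab) != 2L) stopf("labels file must have two columns")
  if (anyDuplicated(lab[[1L]]))
    stopf("duplicated cell_id in labels file: %s",
          lab[[1L]][duplicated(lab[[1L]])][1L])
  miss <- setdiff(cellIds, lab[[1L]])
  if (length(miss) > 0L)
    stopf("missing label for cell_id '%s'", miss[1L])
  labels <- lab[[2L]][match(cellIds, lab[[1L]])]
  newCellDataset(mat, geneNames, cellIds, labels)
}

#' Write a labelled expression dataset to disk
#'
#' Inverse of [readCellDataset()]; writes the counts assay (never the
#' log-transformed one) plus the labels file.
#'
#' @param sce a labelled dataset from [newCellDataset()].
#' @param prefix path prefix for the output files.
#' @param format `"dense_tsv"` or `"mtx"`.
#' @return invisibly, a named list of the written paths.
#' @export
writeCellDataset <- function(sce, prefix, format = c("dense_tsv", "mtx")) {
  format <- match.arg(format)
  counts <- SummarizedExperiment::assay(sce, "counts")
  labPath <- paste0(prefix, "labels.tsv")
  write.table(data.frame(colnames(counts), sce$cellType),
              labPath, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  if (format == "dense_tsv") {
    matPath <- paste0(prefix, "matrix.tsv")
    tab <- data.frame(cell_id = colnames(counts), t(counts),
                      check.names = FALSE)
    write.table(tab, matPath, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- list(matrix = matPath, labels = labPath)
  } else {
    matPath <- paste0(prefix, "matrix.mtx")
    Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                "generalMatrix"), matPath)
    genesPath <- paste0(prefix, "genes.tsv")
    barcodesPath <- paste0(prefix, "barcodes.tsv")
    writeLines(rownames(counts), genesPath)
    writeLines(colnames(counts), barcodesPath)
    paths <- list(matrix = matPath, genes = genesPath,
                  barcodes = barcodesPath, labels = labPath)
  }
  invisible(paths)
}

#' Accessors for labelled cell datasets
#'
#' `cellMatrix()` returns the active expression matrix as cells x genes
#' (the log-transformed assay once [logTransform()] has run),
#' `cellTypes()` the per-cell labels, and `isLogTransformed()` the
#' transform flag.
#'
#' @param sce a labelled dataset from [newCellDataset()].
#' @return `cellMatrix()`: numeric matrix; `cellTypes()`: character
#'   vector; `isLogTransformed()`: logical flag.
#' @export
cellMatrix <- function(sce) {
  nm <- if (isLogTransformed(sce)) "logcounts" else "counts"
  t(as.matrix(SummarizedExperiment::assay(sce, nm)))
}

#' @rdname cellMatrix
#' @export
cellTypes <- function(sce) as.character(sce$cellType)

#' @rdname cellMatrix
#' @export
isLogTransformed <- function(sce)
  isTRUE(S4Vectors::metadata(sce)$logTransformed)

#' Log-transform an expression dataset
#'
#' Replaces every entry x by ln(1 + x), stored as the `"logcounts"`
#' assay, and flips the `logTransformed` flag. Applying it twice is an
#' error.
#'
#' @param sce a labelled dataset from [newCellDataset()].
#' @return the dataset with assay `"logcounts"` and the flag set.
#' @export
logTransform <- function(sce) {
  if (isLogTransformed(sce))
    stopf("dataset is already log-transformed")
  SummarizedExperiment::assay(sce, "logcounts") <-
    log1p(SummarizedExperiment::assay(sce, "counts"))
  S4Vectors::metadata(sce)$logTransformed <- TRUE
  sce
}

#' Stratified validation/fold split
#'
#' Holds out `validationFraction` of the cells for encoder selection and
#' deals the remainder into `nFolds` cross-validation folds, per class:
#' cells of each class are shuffled under the seed, a rounded share goes
#' to the validation set, and the rest are dealt round-robin to the
#' folds, so class proportions are preserved within rounding everywhere.
#'
#' @param x a labelled dataset from [newCellDataset()], or a label vector.
#' @param validationFraction fraction held out (default 0.2).
#' @param nFolds number of folds over the remaining cells (default 5).
#' @param seed integer seed; the split is deterministic given it.
#' @return a [DatasetSplit-class] object.
#' @export
stratifiedSplit <- function(x, validationFraction = 0.2, nFolds = 5L,
                            seed = 1L) {
  labels <- if (methods::is(x, "SummarizedExperiment")) cellTypes(x)
            else as.character(x)
  nFolds <- as.integer(nFolds)
  n <- length(labels)
  counts <- table(labels)
  small <- names(counts)[counts < nFolds + 1L]
  if (length(small) > 0L)
    stopf("class '%s' has %d cells; need at least %d (nFolds + 1)",
          small[1L], counts[[small[1L]]], nFolds + 1L)
  valIdx <- integer(0)
  foldOf <- integer(0)
  classes <- sort(names(counts))
  withSeed(deriveSeed(seed, 1L), {
    for (k in seq_along(classes)) {
      idx <- which(labels == classes[k])
      idx <- idx[sample.int(length(idx))]
      nv <- round(validationFraction * length(idx))
      valIdx <- c(valIdx, idx[seq_len(nv)])
      rest <- idx[setdiff(seq_along(idx), seq_len(nv))]
      if (length(rest) > 0L) {
        # rotate the starting fold per class so fold totals stay even
        f <- ((seq_along(rest) - 1L + (k - 1L)) %% nFolds) + 1L
        names(f) <- rest
        foldOf <- c(foldOf, f)
      }
    }
  })
  foldOf <- foldOf[order(as.integer(names(foldOf)))]
  new("DatasetSplit", nCells = n, validationIdx = sort(valIdx),
      foldAssignments = foldOf, nFolds = nFolds, seed = as.integer(seed))
}

#' @rdname stratifiedSplit
#' @param split a [DatasetSplit-class] object.
#' @export
validationIndices <- function(split) split@validationIdx

#' @rdname stratifiedSplit
#' @param fold fold number in 1..nFolds.
#' @export
foldIndices <- function(split, fold) {
  as.integer(names(split@foldAssignments)[split@foldAssignments == fold])
}

#' @rdname stratifiedSplit
#' @export
trainingIndices <- function(split)
  as.integer(names(split@foldAssignments))

#' Shuffle training cells into mini-batches
#'
#' Shuffles `indices` with a generator keyed by `(seed, epoch)` and
#' chunks them into consecutive blocks of `m`. A final block of size 1
#' is dropped for that epoch (it could contribute no pairs); a final
#' block of 2 or more is kept.
#'
#' @param indices integer cell indices to batch.
#' @param labels labels aligned with `indices`.
#' @param m batch size (>= 2).
#' @param seed integer seed.
#' @param epoch epoch number; reshuffles every epoch.
#' @return list of batches, each `list(indices, labels, batchId)`.
#' @export
makeBatches <- function(indices, labels, m, seed, epoch) {
  if (m < 2L) stopf("batch size m must be >= 2")
  stopifnot(length(indices) == length(labels))
  ord <- withSeed(deriveSeed(seed, 1000L + epoch),
                  sample.int(length(indices)))
  idx <- indices[ord]
  lab <- as.character(labels)[ord]
  starts <- seq(1L, length(idx), by = m)
  batches <- list()
  for (k in seq_along(starts)) {
    span <- starts[k]:min(starts[k] + m - 1L, length(idx))
    if (length(span) < 2L) next
    batches[[length(batches) + 1L]] <-
      list(indices = idx[span], labels = lab[span],
           batchId = length(batches) + 1L)
  }
  batches
}
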