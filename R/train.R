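## The contrastive training loop with MCC-driven encoder selection.
##
## Per epoch, training cells are reshuffled into mini-batches; for each
## batch the encoder and projector run forward in training mode, the
## contrastive batch loss and its gradient are computed on the
## projections, and both networks take one Adam step (gradient step per
## batch). Every selectionInterval epochs the current encoder is frozen
## (evaluation mode, running batch-norm statistics), training cells and
## the held-out validation cells are embedded, an SVM grid search is
## fitted on the training representations, and the validation MCC is
## recorded; the checkpoint with the highest validation MCC (earliest
## epoch on ties) becomes the returned encoder.

embedWithNet <- function(net, X) networkForward(net, X, train = FALSE)$out

#' Train an encoder by augmentation-free supervised contrastive learning
#'
#' @param sce a log-transformed labelled dataset (see [logTransform()]).
#' @param split a [DatasetSplit-class] over the cells of `sce`; the
#'   validation cells are used only for encoder selection.
#' @param cfg a [TrainConfig-class].
#' @param spec a [NetworkSpec-class]; defaults to `NetworkSpec(nGenes)`.
#' @param trainIdx cells to train on; defaults to all non-validation
#'   cells (the pooled folds). Pass a subset (e.g. 4 of 5 folds) for
#'   per-fold cross-validation runs.
#' @param selectionGrid SVM grid used at selection checkpoints; defaults
#'   to a compact linear/RBF grid (the full [defaultSvmGrid()] is meant
#'   for final evaluation).
#' @param verbose print per-epoch progress.
#' @return a [TrainedEncoder-class].
#' @export
trainEncoder <- function(sce, split, cfg, spec = NULL, trainIdx = NULL,
                         selectionGrid = selectionSvmGrid(),
                         verbose = FALSE) {
  stopifnot(methods::is(cfg, "TrainConfig"))
  methods::validObject(cfg)
  if (!isLogTransformed(sce))
    stopf("dataset must be log-transformed before training")
  X <- cellMatrix(sce)
  labels <- cellTypes(sce)
  if (split@nCells != nrow(X))
    stopf("split covers %d cells but the dataset has %d", split@nCells,
          nrow(X))
  if (is.null(trainIdx)) trainIdx <- trainingIndices(split)
  valIdx <- validationIndices(split)
  if (length(unique(labels[trainIdx])) < 2L)
    stopf("training cells must contain at least two classes")
  if (is.null(spec)) spec <- NetworkSpec(ncol(X))
  methods::validObject(spec)
  if (spec@encoderLayers[1L] != ncol(X))
    stopf("spec expects %d genes but the dataset has %d",
          spec@encoderLayers[1L], ncol(X))

  nets <- buildNetworks(spec, cfg@seed)
  encoder <- nets$encoder
  projector <- nets$projector
  stEnc <- newAdamState(encoder)
  stProj <- newAdamState(projector)
  step <- 0L

  trainLog <- data.frame(epoch = integer(0), meanLoss = numeric(0))
  selRecord <- data.frame(epoch = integer(0), mcc = numeric(0))
  best <- list(mcc = -Inf, epoch = NA_integer_, encoder = NULL)

  for (epoch in seq_len(cfg@epochs)) {
    batches <- makeBatches(trainIdx, labels[trainIdx], cfg@batchSize,
                           cfg@seed, epoch)
    epochLoss <- 0
    for (bt in batches) {
      Xb <- X[bt$indices, , drop = FALSE]
      fe <- networkForward(encoder, Xb, train = TRUE)
      encoder <- fe$net
      fp <- networkForward(projector, fe$out, train = TRUE)
      projector <- fp$net
      lg <- batchLossGradient(fp$out, bt$labels, cfg@temperature,
                              cfg@lossVariant)
      if (!is.finite(lg$value))
        stopf("non-finite loss at epoch %d, batch %d", epoch, bt$batchId)
      bp <- networkBackward(projector, fp$caches, lg$grad)
      be <- networkBackward(encoder, fe$caches, bp$dx)
      step <- step + 1L
      up <- adamStep(projector, bp$grads, stProj, step,
                     cfg@learningRate, cfg@weightDecay)
      projector <- up$net; stProj <- up$state
      up <- adamStep(encoder, be$grads, stEnc, step,
                     cfg@learningRate, cfg@weightDecay)
      encoder <- up$net; stEnc <- up$state
      epochLoss <- epochLoss + lg$value
    }
    meanLoss <- if (length(batches) > 0L) epochLoss / length(batches)
                else NA_real_
    trainLog <- rbind(trainLog,
                      data.frame(epoch = epoch, meanLoss = meanLoss))
    if (verbose)
      message(sprintf("epoch %d  mean loss %.5f", epoch, meanLoss))

    if (epoch %% cfg@selectionInterval == 0L) {
      Ztr <- embedWithNet(encoder, X[trainIdx, , drop = FALSE])
      Zval <- embedWithNet(encoder, X[valIdx, , drop = FALSE])
      fit <- svmGridSearch(Ztr, labels[trainIdx], selectionGrid,
                           seed = deriveSeed(cfg@seed, 6L))
      mccVal <- mccScore(labels[valIdx],
                         as.character(predict(fit$model, Zval)))
      selRecord <- rbind(selRecord,
                         data.frame(epoch = epoch, mcc = mccVal))
      if (verbose)
        message(sprintf("  checkpoint epoch %d  validation MCC %.4f",
                        epoch, mccVal))
      if (mccVal > best$mcc + 1e-12) {   # strict: earliest epoch on ties
        best <- list(mcc = mccVal, epoch = epoch, encoder = encoder)
      }
    }
  }
  if (is.null(best$encoder))
    stopf("no selection checkpoint was reached; lower selectionInterval")
  new("TrainedEncoder", weights = best$encoder, spec = spec,
      selectionRecord = selRecord, bestEpoch = best$epoch,
      bestMcc = best$mcc, trainLog = trainLog,
      geneNames = colnames(X) %||% paste0("gene", seq_len(ncol(X))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Embed cells with a trained encoder
#'
#' Deterministic forward pass of the frozen encoder in evaluation mode
#' (batch normalisation uses running statistics), returning the
#' representation-layer output — not the projector output, which exists
#' only for the loss.
#'
#' @param enc a [TrainedEncoder-class].
#' @param x a log-transformed labelled dataset with the training gene
#'   set and order, or a cells x genes numeric matrix.
#' @return a cells x representation-dim numeric matrix.
#' @export
embedCells <- function(enc, x) {
  stopifnot(methods::is(enc, "TrainedEncoder"))
  if (methods::is(x, "SummarizedExperiment")) {
    if (!isLogTransformed(x))
      stopf("dataset must be log-transformed before embedding")
    X <- cellMatrix(x)
  } else {
    X <- as.matrix(x)
  }
  if (ncol(X) != length(enc@geneNames))
    stopf("encoder expects %d genes but input has %d",
          length(enc@geneNames), ncol(X))
  embedWithNet(enc@weights, X)
}
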