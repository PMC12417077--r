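## S4 containers for the contrastive-learning workflow.

#' DatasetSplit: held-out validation set plus stratified cross-validation folds
#'
#' Partition of the cells of a dataset into a held-out validation set
#' (used only for encoder selection) and `nFolds` stratified folds over
#' the remaining cells. Every cell belongs to exactly one of the two.
#'
#' @slot nCells total number of cells the split covers.
#' @slot validationIdx integer indices of the validation cells.
#' @slot foldAssignments integer vector, one entry per non-validation
#'   cell, named by cell index, giving the fold (1..nFolds).
#' @slot nFolds number of folds.
#' @slot seed integer seed the split was derived from.
#' @export
setClass("DatasetSplit",
  representation(
    nCells = "integer",
    validationIdx = "integer",
    foldAssignments = "integer",
    nFolds = "integer",
    seed = "integer"
  )
)

setValidity("DatasetSplit", function(object) {
  fold_idx <- as.integer(names(object@foldAssignments))
  all_idx <- sort(c(object@validationIdx, fold_idx))
  if (length(intersect(object@validationIdx, fold_idx)) > 0L)
    return("validation cells and fold cells overlap")
  if (!identical(all_idx, seq_len(object@nCells)))
    return("validation + folds do not partition the cells")
  if (any(object@foldAssignments < 1L | object@foldAssignments > object@nFolds))
    return("fold assignment outside 1..nFolds")
  TRUE
})

#' @describeIn DatasetSplit-class compact display
#' @param object a `DatasetSplit`
#' @export
setMethod("show", "DatasetSplit", function(object) {
  cat(sprintf(
    "DatasetSplit: %d cells = %d validation + %d training in %d folds (seed %d)\n",
    object@nCells, length(object@validationIdx),
    length(object@foldAssignments), object@nFolds, object@seed))
})

#' NetworkSpec: encoder/projector architecture
#'
#' Layer widths for the encoder and projector multi-layer perceptrons.
#' Hidden layers use ReLU (optionally preceded by batch normalisation);
#' the last layer of each network is linear. Defaults follow the
#' four-layer encoder (three 1024-d hidden layers, 512-d representation
#' layer) and the projection head (256-d hidden, 128-d output).
#'
#' @slot encoderLayers integer vector of widths, input first.
#' @slot projectorLayers integer vector of widths, input first.
#' @slot batchNorm logical, batch-normalise hidden layers.
#' @export
setClass("NetworkSpec",
  representation(
    encoderLayers = "integer",
    projectorLayers = "integer",
    batchNorm = "logical"
  )
)

setValidity("NetworkSpec", function(object) {
  if (length(object@encoderLayers) < 2L || length(object@projectorLayers) < 2L)
    return("encoder and projector need at least input and output widths")
  if (any(c(object@encoderLayers, object@projectorLayers) < 1L))
    return("all layer sizes must be >= 1")
  enc_out <- object@encoderLayers[length(object@encoderLayers)]
  if (enc_out != object@projectorLayers[1L])
    return("encoder output dim must equal projector input dim")
  TRUE
})

#' @describeIn NetworkSpec-class compact display
#' @param object a `NetworkSpec`
#' @export
setMethod("show", "NetworkSpec", function(object) {
  cat("NetworkSpec\n")
  cat("  encoder:  ", paste(object@encoderLayers, collapse = " -> "), "\n")
  cat("  projector:", paste(object@projectorLayers, collapse = " -> "), "\n")
  cat("  batchNorm:", object@batchNorm, "\n")
})

#' Construct a NetworkSpec
#'
#' @param inputDim number of genes the encoder consumes.
#' @param encoderHidden widths of the encoder hidden layers.
#' @param representationDim width of the encoder output (representation)
#'   layer used for downstream tasks.
#' @param projectorHidden widths of the projector hidden layers.
#' @param projectionDim width of the projector output, where the
#'   contrastive loss is computed.
#' @param batchNorm batch-normalise hidden layers (default TRUE).
#' @return a [NetworkSpec-class] object.
#' @export
NetworkSpec <- function(inputDim,
                        encoderHidden = c(1024L, 1024L, 1024L),
                        representationDim = 512L,
                        projectorHidden = 256L,
                        projectionDim = 128L,
                        batchNorm = TRUE) {
  new("NetworkSpec",
      encoderLayers = as.integer(c(inputDim, encoderHidden, representationDim)),
      projectorLayers = as.integer(c(representationDim, projectorHidden,
                                     projectionDim)),
      batchNorm = isTRUE(batchNorm))
}

#' TrainConfig: contrastive-training hyperparameters
#'
#' Defaults follow the training protocol: batch size 64, 500 epochs,
#' temperature 0.1, Adam with learning rate 1e-3 and weight decay 1e-6,
#' encoder selection every 5 epochs.
#'
#' @slot batchSize mini-batch size m.
#' @slot epochs number of training epochs.
#' @slot temperature softmax temperature tau (> 0).
#' @slot learningRate Adam learning rate.
#' @slot weightDecay Adam weight decay (L2 added to the gradient).
#' @slot selectionInterval epochs between encoder-selection checkpoints.
#' @slot lossVariant `"afrcl"` (restricted denominator) or `"supcon"`
#'   (conventional supervised contrastive denominator).
#' @slot seed integer seed controlling initialisation and batching.
#' @export
setClass("TrainConfig",
  representation(
    batchSize = "integer",
    epochs = "integer",
    temperature = "numeric",
    learningRate = "numeric",
    weightDecay = "numeric",
    selectionInterval = "integer",
    lossVariant = "character",
    seed = "integer"
  )
)

setValidity("TrainConfig", function(object) {
  if (object@batchSize < 2L) return("batchSize must be >= 2")
  if (object@epochs < 1L) return("epochs must be >= 1")
  if (object@temperature <= 0) return("temperature must be > 0")
  if (object@learningRate <= 0) return("learningRate must be > 0")
  if (object@weightDecay < 0) return("weightDecay must be >= 0")
  if (object@selectionInterval < 1L || object@selectionInterval > object@epochs)
    return("selectionInterval must be in 1..epochs")
  if (!object@lossVariant %in% c("afrcl", "supcon"))
    return("lossVariant must be 'afrcl' or 'supcon'")
  TRUE
})

#' @describeIn TrainConfig-class compact display
#' @param object a `TrainConfig`
#' @export
setMethod("show", "TrainConfig", function(object) {
  cat(sprintf(
    "TrainConfig: m=%d epochs=%d tau=%g lr=%g wd=%g select every %d (%s, seed %d)\n",
    object@batchSize, object@epochs, object@temperature, object@learningRate,
    object@weightDecay, object@selectionInterval, object@lossVariant,
    object@seed))
})

#' Construct a TrainConfig
#'
#' @param batchSize mini-batch size (default 64).
#' @param epochs training epochs (default 500).
#' @param temperature contrastive temperature (default 0.1).
#' @param learningRate Adam learning rate (default 1e-3).
#' @param weightDecay Adam weight decay (default 1e-6).
#' @param selectionInterval checkpoint spacing in epochs (default 5).
#' @param lossVariant `"afrcl"` or `"supcon"`.
#' @param seed integer seed.
#' @return a [TrainConfig-class] object.
#' @export
TrainConfig <- function(batchSize = 64L, epochs = 500L, temperature = 0.1,
                        learningRate = 1e-3, weightDecay = 1e-6,
                        selectionInterval = 5L,
                        lossVariant = c("afrcl", "supcon"), seed = 1L) {
  lossVariant <- match.arg(lossVariant)
  new("TrainConfig",
      batchSize = as.integer(batchSize), epochs = as.integer(epochs),
      temperature = as.numeric(temperature),
      learningRate = as.numeric(learningRate),
      weightDecay = as.numeric(weightDecay),
      selectionInterval = as.integer(selectionInterval),
      lossVariant = lossVariant, seed = as.integer(seed))
}

#' SyntheticConfig: parameters of the synthetic scRNA-Seq generator
#'
#' @slot nCells number of cells.
#' @slot nGenes number of genes.
#' @slot nTypes number of cell types.
#' @slot proportions per-type sampling probabilities (sum to 1).
#' @slot signatureSize signature genes per type (disjoint blocks).
#' @slot logFoldShift natural-log fold change added to the mean of a
#'   cell's own signature genes (>= 0; class-separation strength).
#' @slot baselineMean negative-binomial mean of background genes (> 0).
#' @slot dispersion negative-binomial dispersion (> 0; variance is
#'   mu + dispersion * mu^2).
#' @slot dropoutRate probability in [0, 1) of zeroing any count.
#' @slot seed integer seed.
#' @export
setClass("SyntheticConfig",
  representation(
    nCells = "integer",
    nGenes = "integer",
    nTypes = "integer",
    proportions = "numeric",
    signatureSize = "integer",
    logFoldShift = "numeric",
    baselineMean = "numeric",
    dispersion = "numeric",
    dropoutRate = "numeric",
    seed = "integer"
  )
)

setValidity("SyntheticConfig", function(object) {
  if (length(object@proportions) != object@nTypes)
    return("proportions must have one entry per type")
  if (abs(sum(object@proportions) - 1) > 1e-9)
    return("proportions must sum to 1 (tolerance 1e-9)")
  if (any(object@proportions <= 0)) return("proportions must be positive")
  if (object@nTypes * object@signatureSize > object@nGenes)
    return("nTypes * signatureSize must be <= nGenes")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    return("dropoutRate must be in [0, 1)")
  if (object@dispersion <= 0) return("dispersion must be > 0")
  if (object@baselineMean <= 0) return("baselineMean must be > 0")
  if (object@logFoldShift < 0) return("logFoldShift must be >= 0")
  TRUE
})

#' @describeIn SyntheticConfig-class compact display
#' @param object a `SyntheticConfig`
#' @export
setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf(
    "SyntheticConfig: %d cells x %d genes, %d types (shift %g, dropout %g, seed %d)\n",
    object@nCells, object@nGenes, object@nTypes, object@logFoldShift,
    object@dropoutRate, object@seed))
})

#' Construct a SyntheticConfig
#'
#' @param nCells,nGenes,nTypes dataset dimensions.
#' @param proportions per-type probabilities; default uniform.
#' @param signatureSize signature genes per type.
#' @param logFoldShift log-scale mean shift on a type's own signatures.
#' @param baselineMean background negative-binomial mean.
#' @param dispersion negative-binomial dispersion.
#' @param dropoutRate independent zeroing probability.
#' @param seed integer seed.
#' @return a [SyntheticConfig-class] object.
#' @export
SyntheticConfig <- function(nCells, nGenes, nTypes,
                            proportions = rep(1 / nTypes, nTypes),
                            signatureSize = 50L, logFoldShift = 2,
                            baselineMean = 0.5, dispersion = 0.5,
                            dropoutRate = 0.3, seed = 1L) {
  new("SyntheticConfig",
      nCells = as.integer(nCells), nGenes = as.integer(nGenes),
      nTypes = as.integer(nTypes), proportions = as.numeric(proportions),
      signatureSize = as.integer(signatureSize),
      logFoldShift = as.numeric(logFoldShift),
      baselineMean = as.numeric(baselineMean),
      dispersion = as.numeric(dispersion),
      dropoutRate = as.numeric(dropoutRate), seed = as.integer(seed))
}

#' TrainedEncoder: frozen encoder plus its selection record
#'
#' @slot weights encoder layer list (opaque; consumed by [embedCells()]).
#' @slot spec the [NetworkSpec-class] the encoder was built from.
#' @slot selectionRecord data.frame with columns `epoch`, `mcc`: the
#'   validation MCC measured at every selection checkpoint.
#' @slot bestEpoch earliest epoch achieving the maximal validation MCC.
#' @slot bestMcc the maximal validation MCC.
#' @slot trainLog data.frame with columns `epoch`, `meanLoss`.
#' @slot geneNames gene names (order) the encoder expects.
#' @export
setClass("TrainedEncoder",
  representation(
    weights = "list",
    spec = "NetworkSpec",
    selectionRecord = "data.frame",
    bestEpoch = "integer",
    bestMcc = "numeric",
    trainLog = "data.frame",
    geneNames = "character"
  )
)

setValidity("TrainedEncoder", function(object) {
  rec <- object@selectionRecord
  if (nrow(rec) == 0L) return("selectionRecord is empty")
  if (!all(c("epoch", "mcc") %in% names(rec)))
    return("selectionRecord needs columns epoch, mcc")
  if (abs(object@bestMcc - max(rec$mcc)) > 1e-12)
    return("bestMcc must equal the maximum recorded validation MCC")
  earliest <- min(rec$epoch[rec$mcc >= max(rec$mcc) - 1e-12])
  if (object@bestEpoch != earliest)
    return("bestEpoch must be the earliest epoch achieving bestMcc")
  TRUE
})

#' @describeIn TrainedEncoder-class compact display
#' @param object a `TrainedEncoder`
#' @export
setMethod("show", "TrainedEncoder", function(object) {
  cat(sprintf(
    "TrainedEncoder: %d genes -> %d-d representation; best validation MCC %.4f at epoch %d (%d checkpoints)\n",
    length(object@geneNames),
    object@spec@encoderLayers[length(object@spec@encoderLayers)],
    object@bestMcc, object@bestEpoch, nrow(object@selectionRecord)))
})

#' PredictionSet: paired ground-truth and predicted labels
#'
#' @slot yTrue character vector of true labels.
#' @slot yPred character vector of predicted labels.
#' @slot classAlphabet ordered set of admissible labels.
#' @export
setClass("PredictionSet",
  representation(
    yTrue = "character",
    yPred = "character",
    classAlphabet = "character"
  )
)

setValidity("PredictionSet", function(object) {
  if (length(object@yTrue) != length(object@yPred))
    return("yTrue and yPred must have equal length")
  if (length(object@yTrue) < 1L) return("need at least one prediction")
  if (anyDuplicated(object@classAlphabet))
    return("classAlphabet has duplicated labels")
  if (!all(object@yTrue %in% object@classAlphabet))
    return("yTrue contains labels outside the class alphabet")
  if (!all(object@yPred %in% object@classAlphabet))
    return("yPred contains labels outside the class alphabet")
  TRUE
})

#' @describeIn PredictionSet-class compact display
#' @param object a `PredictionSet`
#' @export
setMethod("show", "PredictionSet", function(object) {
  cat(sprintf("PredictionSet: %d instances, %d classes, accuracy %.4f\n",
              length(object@yTrue), length(object@classAlphabet),
              mean(object@yTrue == object@yPred)))
})

#' Construct a PredictionSet
#'
#' @param yTrue true labels (character or factor).
#' @param yPred predicted labels.
#' @param classAlphabet ordered label set; defaults to the sorted union
#'   of labels seen in `yTrue` and `yPred`.
#' @return a [PredictionSet-class] object.
#' @export
PredictionSet <- function(yTrue, yPred, classAlphabet = NULL) {
  yTrue <- as.character(yTrue)
  yPred <- as.character(yPred)
  if (is.null(classAlphabet))
    classAlphabet <- sort(unique(c(yTrue, yPred)))
  new("PredictionSet", yTrue = yTrue, yPred = yPred,
      classAlphabet = as.character(classAlphabet))
}
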