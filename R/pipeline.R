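## End-to-end protocols: log transform -> stratified split -> contrastive
## training with MCC-driven selection -> embedding -> classification ->
## metrics -> uniformity/tolerance diagnostics, plus the head-to-head
## comparison of the restricted loss against the conventional
## supervised contrastive loss on shared seeds and splits.

protocolKeys <- c(
  "batchSize", "epochs", "temperature", "learningRate", "weightDecay",
  "selectionInterval", "lossVariant", "seed", "seeds",
  "validationFraction", "nFolds", "cv", "classifier", "knnK",
  "encoderHidden", "representationDim", "projectorHidden",
  "projectionDim", "batchNorm", "t")

#' Protocol configuration
#'
#' Flat key/value configuration consumed by [runProtocol()] and
#' [compareVariants()]. `protocolConfig()` fills desk-scale defaults
#' (60 epochs; paper-scale training uses `epochs = 500`);
#' `readProtocolConfig()` loads a YAML file of the same flat keys and
#' rejects unknown keys.
#'
#' @param ... overrides of the default keys (see `protocolKeys` in the
#'   source; unknown keys error).
#' @return a named list.
#' @export
protocolConfig <- function(...) {
  cfg <- list(
    batchSize = 64L, epochs = 60L, temperature = 0.1,
    learningRate = 1e-3, weightDecay = 1e-6, selectionInterval = 5L,
    lossVariant = "afrcl", seed = 1L, seeds = NULL,
    validationFraction = 0.2, nFolds = 5L, cv = TRUE,
    classifier = "svm", knnK = 5L,
    encoderHidden = c(1024L, 1024L, 1024L), representationDim = 512L,
    projectorHidden = 256L, projectionDim = 128L, batchNorm = TRUE,
    t = 2)
  over <- list(...)
  unknown <- setdiff(names(over), protocolKeys)
  if (length(unknown) > 0L)
    stopf("unknown config key: %s", unknown[1L])
  modifyList(cfg, over)
}

#' @rdname protocolConfig
#' @param path path to a flat YAML config file.
#' @export
readProtocolConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(protocolConfig, vals)
}

trainConfigFrom <- function(cfg, seed = cfg$seed,
                            lossVariant = cfg$lossVariant) {
  TrainConfig(batchSize = cfg$batchSize, epochs = cfg$epochs,
              temperature = cfg$temperature,
              learningRate = cfg$learningRate,
              weightDecay = cfg$weightDecay,
              selectionInterval = cfg$selectionInterval,
              lossVariant = lossVariant, seed = seed)
}

networkSpecFrom <- function(cfg, inputDim) {
  NetworkSpec(inputDim, encoderHidden = cfg$encoderHidden,
              representationDim = cfg$representationDim,
              projectorHidden = cfg$projectorHidden,
              projectionDim = cfg$projectionDim,
              batchNorm = cfg$batchNorm)
}

configDigest <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  keep <- cfg[order(names(cfg))]
  writeLines(yaml::as.yaml(keep), tmp)
  unname(tools::md5sum(tmp))
}

loadInput <- function(x, labelsPath, format) {
  if (methods::is(x, "SummarizedExperiment")) return(x)
  readCellDataset(x, labelsPath, format)
}

classifierGrid <- function(cfg) {
  if (cfg$classifier == "knn") list(k = cfg$knnK) else NULL
}

#' Run the full cell-type identification protocol
#'
#' Log-transforms the data (if raw), makes the stratified
#' validation/fold split, then either (default, `cv = TRUE`) trains one
#' encoder per fold on the other folds — each with MCC-driven selection
#' against the shared held-out validation set — and scores the held-out
#' fold, or (`cv = FALSE`) trains a single encoder on the pooled folds
#' and scores the validation set. Finishes with uniformity/tolerance
#' diagnostics of the best encoder's embeddings over all cells, and
#' writes a metrics table, logs, encoder weights and a run manifest
#' under `outDir`.
#'
#' @param x a labelled dataset (see [newCellDataset()]) or a matrix file
#'   path.
#' @param config a config list from [protocolConfig()].
#' @param outDir output directory (created if missing).
#' @param labelsPath,format forwarded to [readCellDataset()] when `x`
#'   is a path.
#' @return invisibly, the run manifest list; its `metrics` element holds
#'   the per-fold (or validation) metric table and `quality` the
#'   diagnostics.
#' @export
runProtocol <- function(x, config = protocolConfig(), outDir,
                        labelsPath = NULL, format = "dense_tsv") {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  started <- format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  sce <- loadInput(x, labelsPath, format)
  inputDigest <- if (is.character(x)) unname(tools::md5sum(x)) else NA
  if (!isLogTransformed(sce)) sce <- logTransform(sce)
  labels <- cellTypes(sce)
  split <- stratifiedSplit(sce, config$validationFraction, config$nFolds,
                           seed = config$seed)
  spec <- networkSpecFrom(config, ncol(cellMatrix(sce)))
  X <- cellMatrix(sce)
  grid <- classifierGrid(config)

  metrics <- data.frame()
  encoders <- list()
  if (isTRUE(config$cv)) {
    for (f in seq_len(config$nFolds)) {
      testIdx <- foldIndices(split, f)
      trIdx <- setdiff(trainingIndices(split), testIdx)
      cfgF <- trainConfigFrom(config, seed = deriveSeed(config$seed, 10L + f))
      enc <- trainEncoder(sce, split, cfgF, spec, trainIdx = trIdx)
      encoders[[f]] <- enc
      ps <- fitPredictClassifier(
        embedCells(enc, X[trIdx, , drop = FALSE]), labels[trIdx],
        embedCells(enc, X[testIdx, , drop = FALSE]), labels[testIdx],
        kind = config$classifier, grid = grid,
        seed = deriveSeed(config$seed, 20L + f))
      metrics <- rbind(metrics, data.frame(
        fold = f, mcc = mccScore(ps), f1_macro = f1Macro(ps),
        acc = accuracyScore(ps), n_test = length(testIdx),
        val_mcc = enc@bestMcc, best_epoch = enc@bestEpoch))
    }
    metrics <- rbind(metrics, data.frame(
      fold = NA, mcc = mean(metrics$mcc), f1_macro = mean(metrics$f1_macro),
      acc = mean(metrics$acc), n_test = sum(metrics$n_test),
      val_mcc = mean(metrics$val_mcc), best_epoch = NA))
    bestFold <- which.max(metrics$val_mcc[seq_len(config$nFolds)])
    bestEnc <- encoders[[bestFold]]
  } else {
    trIdx <- trainingIndices(split)
    valIdx <- validationIndices(split)
    enc <- trainEncoder(sce, split, trainConfigFrom(config), spec)
    encoders[[1L]] <- enc
    ps <- fitPredictClassifier(
      embedCells(enc, X[trIdx, , drop = FALSE]), labels[trIdx],
      embedCells(enc, X[valIdx, , drop = FALSE]), labels[valIdx],
      kind = config$classifier, grid = grid,
      seed = deriveSeed(config$seed, 20L))
    metrics <- data.frame(
      fold = NA, mcc = mccScore(ps), f1_macro = f1Macro(ps),
      acc = accuracyScore(ps), n_test = length(valIdx),
      val_mcc = enc@bestMcc, best_epoch = enc@bestEpoch)
    bestEnc <- enc
  }

  qual <- qualityProduct(embedCells(bestEnc, X), labels, t = config$t)
  qualityTab <- data.frame(uniformity = qual$uniformity,
                           tolerance = qual$tolerance,
                           product = qual$product,
                           n = nrow(X), n_classes = length(unique(labels)))

  paths <- list(metrics = file.path(outDir, "metrics.tsv"),
                quality = file.path(outDir, "quality.tsv"),
                selection = file.path(outDir, "selection_log.tsv"),
                trainLog = file.path(outDir, "train_log.tsv"),
                encoder = file.path(outDir, "encoder.rds"),
                manifest = file.path(outDir, "manifest.yaml"))
  write.table(metrics, paths$metrics, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(qualityTab, paths$quality, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(bestEnc@selectionRecord, paths$selection, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(bestEnc@trainLog, paths$trainLog, sep = "\t",
              quote = FALSE, row.names = FALSE)
  saveRDS(bestEnc, paths$encoder)

  manifest <- list(
    config = config, configDigest = configDigest(config),
    seed = config$seed, inputDigest = inputDigest,
    outputs = lapply(paths, identity),
    started = started, finished = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    metrics = metrics, quality = qualityTab)
  writeLines(yaml::as.yaml(manifest[c("configDigest", "seed",
                                      "inputDigest", "started",
                                      "finished")]),
             paths$manifest)
  invisible(manifest)
}

#' Head-to-head comparison of the two loss variants
#'
#' Runs the protocol once per seed with the restricted loss ("afrcl")
#' and once with the conventional supervised contrastive loss
#' ("supcon"), sharing the split and all derived seeds, and tabulates
#' paired validation metrics with win/tie/loss flags. Uses the
#' single-encoder (pooled folds) protocol for each run.
#'
#' @inheritParams runProtocol
#' @param variants the two loss variants to pair; passing the same
#'   variant twice is allowed (every comparison then ties).
#' @return invisibly, `list(table, wins)`: the paired per-seed metric
#'   table and the per-metric win/tie/loss counts of the first variant.
#' @export
compareVariants <- function(x, config = protocolConfig(), outDir,
                            labelsPath = NULL, format = "dense_tsv",
                            variants = c("afrcl", "supcon")) {
  stopifnot(length(variants) == 2L,
            all(variants %in% c("afrcl", "supcon")))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  sce <- loadInput(x, labelsPath, format)
  if (!isLogTransformed(sce)) sce <- logTransform(sce)
  seeds <- if (is.null(config$seeds)) config$seed else config$seeds
  rows <- data.frame()
  for (sd in seeds) {
    res <- lapply(seq_along(variants), function(k) {
      cfgV <- modifyList(config, list(seed = as.integer(sd),
                                      lossVariant = variants[k],
                                      cv = FALSE, seeds = NULL))
      runProtocol(sce, cfgV,
                  file.path(outDir, sprintf("%s_%d_seed%s", variants[k],
                                            k, sd)))
    })
    m <- lapply(res, function(r) r$metrics[1L, ])
    for (metric in c("mcc", "f1_macro", "acc")) {
      a <- m[[1L]][[metric]]; b <- m[[2L]][[metric]]
      rows <- rbind(rows, data.frame(
        seed = sd, metric = metric, first = a, second = b,
        outcome = if (abs(a - b) < 1e-12) "tie"
                  else if (a > b) "win" else "loss"))
    }
  }
  wins <- table(factor(rows$outcome, levels = c("win", "tie", "loss")),
                rows$metric)
  write.table(rows, file.path(outDir, "comparison.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(table = rows, wins = wins))
}
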