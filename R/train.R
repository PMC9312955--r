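#' TrainConfig: optimization settings
#'
#' @slot lr Adam learning rate.
#' @slot lrDecay multiplicative learning-rate decay per epoch (1 = constant).
#' @slot warmupEpochs epochs over which the learning rate ramps linearly from
#'   lr/warmupEpochs to lr before decay starts (0 = no warmup). Warmup epochs
#'   are excluded from checkpoint selection and the patience count: the model
#'   has not yet trained at its target learning rate.
#' @slot batchSize minibatch size (segments).
#' @slot maxEpochs maximum training epochs.
#' @slot valFraction fraction of the training subjects' *clips* held out for
#'   validation (the split is always at clip level, never segment level, so
#'   segments of one clip never straddle the split).
#' @slot patience early-stopping patience in epochs without improvement of
#'   the validation AUC.
#' @slot classWeighting logical; inverse-frequency class weights in the
#'   cross-entropy loss.
#' @slot labelSmoothing label-smoothing mass in [0, 0.5): targets are
#'   (1 - labelSmoothing) one-hot plus labelSmoothing / 2 on each class.
#'   Keeps predicted probabilities calibrated as training converges instead
#'   of saturating at 0/1.
#' @slot seed integer seed controlling initialization, shuffling, dropout and
#'   the validation split.
#'
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(
    lr = "numeric", lrDecay = "numeric", warmupEpochs = "integer",
    batchSize = "integer", maxEpochs = "integer", valFraction = "numeric",
    patience = "integer", classWeighting = "logical",
    labelSmoothing = "numeric", seed = "integer"
  )
)

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@lr <= 0) msg <- c(msg, "lr must be > 0")
  if (object@lrDecay <= 0 || object@lrDecay > 1)
    msg <- c(msg, "lrDecay must be in (0, 1]")
  if (object@warmupEpochs < 0L) msg <- c(msg, "warmupEpochs must be >= 0")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@maxEpochs < 1L) msg <- c(msg, "maxEpochs must be >= 1")
  if (object@valFraction <= 0 || object@valFraction >= 1)
    msg <- c(msg, "valFraction must be in (0, 1)")
  if (object@patience < 1L) msg <- c(msg, "patience must be >= 1")
  if (object@labelSmoothing < 0 || object@labelSmoothing >= 0.5)
    msg <- c(msg, "labelSmoothing must be in [0, 0.5)")
  if (length(msg)) msg else TRUE
})

#' Construct a TrainConfig
#' @param lr,lrDecay,warmupEpochs,batchSize,maxEpochs,valFraction,patience,classWeighting,labelSmoothing,seed
#'   see [TrainConfig-class].
#' @return a validated [TrainConfig-class].
#' @export
trainConfig <- function(lr = 2e-3, lrDecay = 0.92, warmupEpochs = 4,
                        batchSize = 32, maxEpochs = 35, valFraction = 0.2,
                        patience = 10, classWeighting = TRUE,
                        labelSmoothing = 0.1, seed = 1L) {
  tryCatch(
    new("TrainConfig", lr = as.numeric(lr), lrDecay = as.numeric(lrDecay),
        warmupEpochs = as.integer(warmupEpochs),
        batchSize = as.integer(batchSize),
        maxEpochs = as.integer(maxEpochs),
        valFraction = as.numeric(valFraction),
        patience = as.integer(patience),
        classWeighting = isTRUE(classWeighting),
        labelSmoothing = as.numeric(labelSmoothing),
        seed = as.integer(seed)),
    error = function(e) stopConfig(conditionMessage(e)))
}

setMethod("show", "TrainConfig", function(object) {
  cat(sprintf(paste0("TrainConfig: lr %g (warmup %d, decay %g/epoch), ",
                     "batch %d, <= %d epochs, val fraction %g, patience %d, ",
                     "class weights %s, seed %d\n"),
              object@lr, object@warmupEpochs, object@lrDecay,
              object@batchSize, object@maxEpochs,
              object@valFraction, object@patience, object@classWeighting,
              object@seed))
})

# Clip-level validation split, stratified by (subject, label). Returns the
# clip ids held out for validation.
validationClips <- function(meta, valFraction) {
  clipTab <- unique(meta[, c("subjectId", "clipId", "label")])
  valIds <- character(0)
  for (s in unique(clipTab$subjectId)) {
    for (lb in unique(clipTab$label)) {
      ids <- sort(clipTab$clipId[clipTab$subjectId == s & clipTab$label == lb])
      if (!length(ids)) next
      nVal <- max(1L, floor(length(ids) * valFraction))
      if (nVal >= length(ids)) nVal <- length(ids) - 1L
      if (nVal > 0L) valIds <- c(valIds, sample(ids, nVal))
    }
  }
  valIds
}

#' Train the MViT on scalogram segments
#'
#' Minimizes class-weighted cross-entropy with Adam. A clip-level validation
#' split (never segment-level, so no clip leaks across the split) is drawn
#' from the training subjects; after every epoch the validation AUC is
#' computed and the best-validation-AUC parameters are kept. Training stops
#' early after `patience` epochs without improvement. Fully determined by
#' `tcfg@seed` and the data.
#'
#' @param x (segments, channels, H, W) array from [scalogramDataset()].
#' @param meta the matching metadata frame (one row per segment).
#' @param mcfg an [MViTConfig-class]; channel count must match `dim(x)[2]`.
#' @param tcfg a [TrainConfig-class].
#' @return list with `params` (best checkpoint), `cfg`, `log` (per-epoch
#'   data.frame of loss and validation AUC), `bestEpoch`, `valClips`.
#' @export
trainMViT <- function(x, meta, mcfg, tcfg = trainConfig()) {
  stopifnot(dim(x)[1] == nrow(meta))
  if (dim(x)[2] != mcfg@nBranches)
    stopConfig("channel count ", dim(x)[2], " does not match nBranches")
  if (!all(dim(x)[3:4] == mcfg@imageShape))
    stopConfig("scalogram shape does not match mcfg imageShape")
  if (length(unique(meta$label)) < 2L)
    stopData("training data must contain both classes")

  localSeed(tcfg@seed, {
    valIds <- validationClips(meta, tcfg@valFraction)
    isVal <- meta$clipId %in% valIds
    trIdx <- which(!isVal)
    vaIdx <- which(isVal)
    if (length(unique(meta$label[trIdx])) < 2L)
      stopData("training split lost a class; lower valFraction")
    y <- ifelse(meta$label == "preictal", 2L, 1L)
    # inverse-frequency class weights, normalized to mean 1 over training rows
    w <- rep(1, nrow(meta))
    if (tcfg@classWeighting) {
      frq <- table(factor(y[trIdx], levels = 1:2)) / length(trIdx)
      w <- 1 / (2 * as.numeric(frq)[y])
    }

    params <- initMViTParams(mcfg, seed = mixSeed(tcfg@seed, 101))
    theta <- flattenParams(params)
    mAdam <- vAdam <- numeric(length(theta))
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    step <- 0L
    bestAuc <- -Inf
    bestTheta <- theta
    bestEpoch <- 0L
    sinceBest <- 0L
    log <- data.frame(epoch = integer(0), loss = numeric(0),
                      valAUC = numeric(0))

    for (epoch in seq_len(tcfg@maxEpochs)) {
      lrEpoch <- if (epoch <= tcfg@warmupEpochs) {
        tcfg@lr * epoch / tcfg@warmupEpochs
      } else {
        tcfg@lr * tcfg@lrDecay^(epoch - tcfg@warmupEpochs)
      }
      ord <- sample(trIdx)
      lossSum <- 0
      nBatch <- 0L
      for (s in seq(1L, length(ord), by = tcfg@batchSize)) {
        ib <- ord[s:min(s + tcfg@batchSize - 1L, length(ord))]
        params <- relistParams(theta, params)
        r <- mvitLossGradFast(x[ib, , , , drop = FALSE], y[ib], w[ib],
                              params, mcfg, train = TRUE,
                              smooth = tcfg@labelSmoothing)
        if (!is.finite(r$loss))
          stopData("training diverged (non-finite loss) at epoch ", epoch)
        gvec <- flattenParams(r$grads)
        step <- step + 1L
        mAdam <- b1 * mAdam + (1 - b1) * gvec
        vAdam <- b2 * vAdam + (1 - b2) * gvec^2
        mh <- mAdam / (1 - b1^step)
        vh <- vAdam / (1 - b2^step)
        theta <- theta - lrEpoch * mh / (sqrt(vh) + eps)
        lossSum <- lossSum + r$loss
        nBatch <- nBatch + 1L
      }
      params <- relistParams(theta, params)
      valProb <- predictProbs(x[vaIdx, , , , drop = FALSE], params, mcfg)
      valAuc <- aucScore(valProb, meta$label[vaIdx] == "preictal")
      if (is.na(valAuc)) valAuc <- 0.5
      log <- rbind(log, data.frame(epoch = epoch, loss = lossSum / nBatch,
                                   valAUC = valAuc))
      if (epoch <= tcfg@warmupEpochs) next # warmup: not eligible as checkpoint
      if (valAuc > bestAuc + 1e-12) {
        bestAuc <- valAuc
        bestTheta <- theta
        bestEpoch <- epoch
        sinceBest <- 0L
      } else {
        sinceBest <- sinceBest + 1L
        if (sinceBest >= tcfg@patience) break
      }
    }
    list(params = relistParams(bestTheta, params), cfg = mcfg, log = log,
         bestEpoch = bestEpoch, valClips = sort(valIds))
  })
}

#' Evaluate a trained model on labeled segments
#'
#' @param model list returned by [trainMViT()] (or a list with `params` and
#'   `cfg`).
#' @param x (segments, channels, H, W) array.
#' @param meta matching metadata frame.
#' @param threshold decision threshold on the preictal probability.
#' @return list with `predictions` (the per-segment prediction set:
#'   subjectId, clipId, segmentIndex, label, probPreictal, segDurS) and
#'   `metrics` (a [MetricsReport-class]).
#' @export
evaluateModel <- function(model, x, meta, threshold = 0.5) {
  probs <- predictProbs(x, model$params, model$cfg)
  predictions <- data.frame(
    subjectId = meta$subjectId, clipId = meta$clipId,
    segmentIndex = meta$segmentIndex, label = meta$label,
    probPreictal = probs, segDurS = meta$segDurS,
    stringsAsFactors = FALSE)
  list(predictions = predictions,
       metrics = computeMetrics(predictions, threshold))
}

#' Leave-one-subject-out folds
#'
#' One fold per subject: the fold's test set is all of that subject's clips,
#' its training set everything else. Folds cover all clips and no subject
#' appears on both sides of a fold.
#'
#' @param subjects character vector of per-clip (or per-segment) subject ids.
#' @return list of folds, each `list(subject, testIdx, trainIdx)`, ordered by
#'   subject id.
#' @export
losoSplits <- function(subjects) {
  uq <- sort(unique(subjects))
  if (length(uq) < 2L)
    stopData("leave-one-subject-out needs at least 2 subjects")
  lapply(uq, function(s)
    list(subject = s, testIdx = which(subjects == s),
         trainIdx = which(subjects != s)))
}

#' Run the full leave-one-subject-out experiment
#'
#' Converts clips to scalogram segments once, then for each subject trains a
#' model on all other subjects' segments and evaluates on the held-out
#' subject. The pooled report is computed over the union of all test-fold
#' prediction sets. Per-fold seeds are derived from `tcfg@seed` and the fold
#' index.
#'
#' @param clips list of [EEGClip-class].
#' @param scfg [ScalogramConfig-class].
#' @param mcfg [MViTConfig-class].
#' @param tcfg [TrainConfig-class].
#' @param threshold decision threshold.
#' @param outDir optional directory; per-fold and pooled reports (JSON) and
#'   the pooled prediction set (CSV) are written there.
#' @param segLenS segment duration in seconds.
#' @return list with `folds` (per-fold list(subject, metrics, log)),
#'   `pooled` ([MetricsReport-class]), `predictions` (pooled data.frame).
#' @export
runLoso <- function(clips, scfg = scalogramConfig(), mcfg, tcfg = trainConfig(),
                    threshold = 0.5, outDir = NULL, segLenS = 10) {
  ds <- scalogramDataset(clips, scfg, segLenS)
  folds <- losoSplits(ds$meta$subjectId)
  foldOut <- list()
  predList <- list()
  for (k in seq_along(folds)) {
    fd <- folds[[k]]
    tk <- new("TrainConfig", lr = tcfg@lr, lrDecay = tcfg@lrDecay,
              warmupEpochs = tcfg@warmupEpochs, batchSize = tcfg@batchSize,
              maxEpochs = tcfg@maxEpochs, valFraction = tcfg@valFraction,
              patience = tcfg@patience, classWeighting = tcfg@classWeighting,
              labelSmoothing = tcfg@labelSmoothing,
              seed = mixSeed(tcfg@seed, k))
    model <- trainMViT(ds$x[fd$trainIdx, , , , drop = FALSE],
                       ds$meta[fd$trainIdx, , drop = FALSE], mcfg, tk)
    ev <- evaluateModel(model, ds$x[fd$testIdx, , , , drop = FALSE],
                        ds$meta[fd$testIdx, , drop = FALSE], threshold)
    foldOut[[k]] <- list(subject = fd$subject, metrics = ev$metrics,
                         log = model$log, bestEpoch = model$bestEpoch)
    predList[[k]] <- ev$predictions
  }
  predictions <- do.call(rbind, predList)
  pooled <- computeMetrics(predictions, threshold)
  res <- list(folds = foldOut, pooled = pooled, predictions = predictions)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeJson(list(
      pooled = metricsToList(pooled),
      folds = lapply(foldOut, function(f)
        c(list(subject = f$subject, best_epoch = f$bestEpoch),
          metricsToList(f$metrics)))),
      file.path(outDir, "loso_report.json"))
    write.csv(predictions, file.path(outDir, "predictions.csv"),
              row.names = FALSE)
  }
  res
}
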