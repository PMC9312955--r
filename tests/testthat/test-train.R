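test_that("leave-one-subject-out folds partition the clips", {
  subj <- c(rep("A", 5), rep("B", 3), rep("C", 7))
  folds <- losoSplits(subj)
  expect_length(folds, 3L)
  # test sizes match each subject's clip count; no subject on both sides
  expect_identical(vapply(folds, function(f) length(f$testIdx), integer(1)),
                   c(5L, 3L, 7L))
  for (f in folds) {
    expect_length(intersect(unique(subj[f$testIdx]),
                            unique(subj[f$trainIdx])), 0L)
    expect_setequal(c(f$testIdx, f$trainIdx), seq_along(subj))
  }
  # union of test sets covers everything exactly once
  expect_setequal(unlist(lapply(folds, `[[`, "testIdx")), seq_along(subj))
  expect_error(losoSplits(rep("A", 4)), class = "mvitDataError")
})

predFrame <- function(prob, label, segDurS = 10) {
  data.frame(subjectId = "S", clipId = "c", segmentIndex = seq_along(prob),
             label = label, probPreictal = prob, segDurS = segDurS)
}

test_that("confusion metrics follow their definitions", {
  # TP=9, FN=1, TN=8, FP=2 -> SENS 0.90, SPEC 0.80, ACC 0.85
  pred <- predFrame(c(rep(0.9, 9), 0.1, rep(0.2, 8), rep(0.8, 2)),
                    c(rep("preictal", 10), rep("interictal", 10)))
  m <- computeMetrics(pred, 0.5)
  expect_equal(m@sens, 0.90)
  expect_equal(m@spec, 0.80)
  expect_equal(m@acc, 0.85)
  expect_equal(unname(m@counts[c("TP", "FN", "TN", "FP")]),
               c(9, 1, 8, 2))
  # ACC is consistent with the confusion counts
  expect_equal(m@acc, (m@counts["TP"] + m@counts["TN"]) / sum(m@counts),
               ignore_attr = TRUE)

  # 2 false positives over 720 interictal 10-s segments (2 h) -> 1.0/h
  pred2 <- predFrame(c(rep(0.9, 2), rep(0.1, 718)), rep("interictal", 720))
  expect_equal(computeMetrics(pred2, 0.5)@fprPerHour, 1.0)

  # a missing class yields NA (undefined), never zero
  m3 <- computeMetrics(predFrame(c(0.2, 0.7), rep("interictal", 2)), 0.5)
  expect_true(is.na(m3@sens))
  expect_true(is.na(m3@auc))
  expect_false(is.na(m3@spec))
  m4 <- computeMetrics(predFrame(c(0.2, 0.7), rep("preictal", 2)), 0.5)
  expect_true(is.na(m4@spec))
  expect_true(is.na(m4@fprPerHour))
})

test_that("AUC equals exhaustive pairwise concordance with half-ties", {
  # spec scores: positives .9, .8; negatives .7, .6, .8 -> (5 + 0.5)/6
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.8)
  pos <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(aucScore(scores, pos), (5 + 0.5) / 6)

  # random case vs an exhaustive double loop
  set.seed(21)
  s <- round(runif(20), 2) # ties likely
  p <- rep(c(TRUE, FALSE), 10)
  conc <- 0
  for (i in which(p)) for (j in which(!p))
    conc <- conc + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
  expect_equal(aucScore(s, p), conc / (sum(p) * sum(!p)))

  # invariance under strictly monotone transforms
  expect_equal(aucScore(qlogis(pmin(pmax(s, 0.01), 0.99)), p),
               aucScore(pmin(pmax(s, 0.01), 0.99), p))
  expect_true(is.na(aucScore(s, rep(TRUE, 20))))

  # ROC endpoints
  roc <- rocCurve(predFrame(s, ifelse(p, "preictal", "interictal")))
  expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[1], 0)
  expect_equal(roc$tpr[nrow(roc)], 1)
  expect_equal(roc$fpr[nrow(roc)], 1)
})

test_that("training reduces the loss and is bit-reproducible", {
  ds <- tinyDataset(seed = 31)
  mcfg <- smallModelCfg(nBranches = 2)
  tcfg <- trainConfig(maxEpochs = 5, patience = 5, warmupEpochs = 1,
                      valFraction = 0.34, seed = 7)
  m1 <- trainMViT(ds$x, ds$meta, mcfg, tcfg)
  expect_lt(tail(m1$log$loss, 1), m1$log$loss[1]) # sanity descent
  expect_true(all(is.finite(m1$log$valAUC)))
  # the validation split is at clip level and stays inside the training side
  expect_true(all(m1$valClips %in% ds$meta$clipId))

  m2 <- trainMViT(ds$x, ds$meta, mcfg, tcfg)
  expect_identical(SeizureMViT:::flattenParams(m1$params),
                   SeizureMViT:::flattenParams(m2$params)) # bit-exact
  expect_identical(m1$log, m2$log)

  # single-class training data is a data error
  metaOne <- ds$meta
  metaOne$label <- "preictal"
  expect_error(trainMViT(ds$x, metaOne, mcfg, tcfg), class = "mvitDataError")
})

test_that("clip-permuted labels give chance-level held-out AUC", {
  ds <- tinyDataset(seed = 41, clipsPerClass = 4)
  mcfg <- smallModelCfg(nBranches = 2)
  testIdx <- which(ds$meta$subjectId == "S02")
  trainIdx <- which(ds$meta$subjectId == "S01")
  aucs <- vapply(1:5, function(sd) {
    meta <- ds$meta
    # permute labels at clip level (segments of a clip move together)
    clipTab <- unique(meta[trainIdx, c("clipId", "label")])
    perm <- localSeedPermute(clipTab$label, sd)
    meta$label[trainIdx] <- perm[match(meta$clipId[trainIdx], clipTab$clipId)]
    model <- trainMViT(ds$x[trainIdx, , , , drop = FALSE],
                       meta[trainIdx, , drop = FALSE], mcfg,
                       trainConfig(maxEpochs = 4, patience = 4,
                                   warmupEpochs = 1, valFraction = 0.3,
                                   seed = sd))
    ev <- evaluateModel(model, ds$x[testIdx, , , , drop = FALSE],
                        ds$meta[testIdx, , drop = FALSE])
    ev$metrics@auc
  }, numeric(1))
  expect_gte(mean(aucs), 0.35)
  expect_lte(mean(aucs), 0.65)
})

test_that("LOSO driver trains one model per subject and pools predictions", {
  clips <- generateDataset(synthConfig(nSubjects = 2, clipsPerClass = 3,
                                       nChannels = 2, fs = 100, clipLenS = 30,
                                       snr = 2, seed = 51))
  res <- runLoso(clips, smallScalCfg(), smallModelCfg(nBranches = 2),
                 trainConfig(maxEpochs = 4, patience = 4, warmupEpochs = 1,
                             valFraction = 0.34, seed = 3),
                 outDir = file.path(tempdir(), "losoOut"))
  expect_length(res$folds, 2L) # 2 subjects -> 2 folds (+ pooled report)
  expect_s4_class(res$pooled, "MetricsReport")

  # pooled predictions = union of the fold test sets; no leakage
  expect_identical(nrow(res$predictions), 36L) # 12 clips x 3 segments
  expect_setequal(unique(res$predictions$subjectId), c("S01", "S02"))

  # pooled confusion counts equal the sum of fold confusion counts
  foldCounts <- Reduce(`+`, lapply(res$folds, function(f) f$metrics@counts))
  expect_identical(res$pooled@counts, foldCounts)

  # metric algebra: reported metrics are reproducible from the stored
  # prediction set at the same threshold
  re <- computeMetrics(res$predictions, 0.5)
  expect_identical(re@counts, res$pooled@counts)
  expect_equal(re@auc, res$pooled@auc)
  expect_equal(re@fprPerHour, res$pooled@fprPerHour)

  # serialized artifacts
  expect_true(file.exists(file.path(tempdir(), "losoOut", "loso_report.json")))
  csv <- read.csv(file.path(tempdir(), "losoOut", "predictions.csv"))
  expect_identical(nrow(csv), 36L)
  expect_true(all(csv$probPreictal >= 0 & csv$probPreictal <= 1))
  unlink(file.path(tempdir(), "losoOut"), recursive = TRUE)
})
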