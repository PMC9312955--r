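#' Rank-based AUC (probability of concordance)
#'
#' AUC = probability that a uniformly random positive score exceeds a
#' uniformly random negative score, ties counted 1/2 (the Mann-Whitney
#' statistic, equal to the trapezoidal area under the ROC curve). Invariant
#' under strictly monotone transforms of the scores.
#'
#' @param scores numeric scores (higher = more preictal).
#' @param positive logical vector, TRUE for preictal.
#' @return AUC in [0, 1], or NA if either class is absent.
#' @export
aucScore <- function(scores, positive) {
  nPos <- sum(positive)
  nNeg <- sum(!positive)
  if (nPos == 0L || nNeg == 0L) return(NA_real_)
  r <- rank(scores) # midranks handle ties as 1/2
  (sum(r[positive]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Compute the metric suite from a prediction set
#'
#' Each evaluated 10-s segment is one decision. At the given threshold:
#' SENS = TP/(TP+FN) over preictal segments, SPEC = TN/(TN+FP) over
#' interictal segments, ACC = (TP+TN)/all, FPR per hour = FP divided by the
#' total interictal hours evaluated (each segment contributes its duration,
#' 10 s = 1/360 h), and AUC is threshold-free. Metrics whose defining class
#' is absent are NA.
#'
#' @param predictions data.frame with columns `label` ("preictal" /
#'   "interictal"), `probPreictal` in [0, 1] and `segDurS` (segment duration,
#'   seconds); the per-segment prediction set produced by [evaluateModel()].
#' @param threshold decision threshold on the preictal probability
#'   (default 0.5; `probPreictal >= threshold` predicts preictal).
#' @return a [MetricsReport-class].
#' @export
computeMetrics <- function(predictions, threshold = 0.5) {
  stopifnot(all(c("label", "probPreictal", "segDurS") %in% names(predictions)))
  pos <- predictions$label == "preictal"
  call <- predictions$probPreictal >= threshold
  TP <- sum(pos & call); FN <- sum(pos & !call)
  FP <- sum(!pos & call); TN <- sum(!pos & !call)
  interHours <- sum(predictions$segDurS[!pos]) / 3600
  new("MetricsReport",
      sens = if (TP + FN > 0) TP / (TP + FN) else NA_real_,
      spec = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
      acc = if (nrow(predictions) > 0) (TP + TN) / nrow(predictions) else NA_real_,
      fprPerHour = if (interHours > 0) FP / interHours else NA_real_,
      auc = aucScore(predictions$probPreictal, pos),
      threshold = threshold,
      counts = c(TP = TP, FN = FN, TN = TN, FP = FP))
}

#' Full ROC curve of a prediction set
#'
#' Sweeps the decision threshold over every distinct score.
#'
#' @param predictions as in [computeMetrics()].
#' @return data.frame with columns `threshold`, `tpr`, `fpr`, ordered by
#'   descending threshold.
#' @export
rocCurve <- function(predictions) {
  pos <- predictions$label == "preictal"
  th <- sort(unique(predictions$probPreictal), decreasing = TRUE)
  th <- c(Inf, th)
  data.frame(
    threshold = th,
    tpr = vapply(th, function(t) mean(predictions$probPreictal[pos] >= t),
                 numeric(1)),
    fpr = vapply(th, function(t) mean(predictions$probPreictal[!pos] >= t),
                 numeric(1)))
}

metricsToList <- function(m) {
  list(sens = m@sens, spec = m@spec, acc = m@acc, fpr_per_hour = m@fprPerHour,
       auc = m@auc, threshold = m@threshold, counts = as.list(m@counts))
}
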