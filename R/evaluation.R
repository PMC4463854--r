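## Classifier validation: leave-one-out cross-validation, confusion-matrix
## metrics, and ROC/AUC from the continuous discriminant scores.

.severity <- c(NC = 1, MCI = 2, AD = 3)

#' Positive class of a diagnostic pair
#'
#' The more impaired diagnosis of the pair is treated as the positive class
#' (AD in AD/NC and AD/MCI; MCI in MCI/NC).
#'
#' @param labels character vector containing exactly two distinct
#'   diagnoses from NC/MCI/AD (or any two labels; falls back to the
#'   lexicographically larger one with a message).
#' @return The positive-class label.
#' @export
positiveClassOf <- function(labels) {
  u <- sort(unique(as.character(labels)))
  if (length(u) != 2) stop("exactly two classes are required")
  if (all(u %in% names(.severity))) u[which.max(.severity[u])]
  else { message("unknown diagnosis labels; using '", u[2], "' as positive"); u[2] }
}

#' Confusion-matrix metrics
#'
#' Accuracy = (TP+TN)/N, sensitivity = TP/(TP+FN) (true positive fraction),
#' specificity = TN/(TN+FP) (true negative proportion). A metric whose
#' denominator is empty (no positives or no negatives in the truth) is
#' reported as NA, not 0.
#'
#' @param predicted,truth vectors of class labels (equal length).
#' @param positiveClass the label counted as positive.
#' @return List with `accuracy`, `sensitivity`, `specificity` and the
#'   confusion counts `tp`, `fp`, `tn`, `fn`.
#' @export
confusionMetrics <- function(predicted, truth, positiveClass) {
  stopifnot(length(predicted) == length(truth))
  pp <- predicted == positiveClass; tp_ <- truth == positiveClass
  tp <- sum(pp & tp_); fn <- sum(!pp & tp_)
  fp <- sum(pp & !tp_); tn <- sum(!pp & !tp_)
  list(accuracy = (tp + tn) / length(truth),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' ROC curve and AUC from continuous scores
#'
#' Sweeps a threshold over the unique score values (higher score = more
#' positive), collecting (1 - specificity, sensitivity) points, and
#' integrates the area under the curve by the trapezoidal rule — equal to
#' the Mann-Whitney concordance probability, with ties counted 1/2.
#'
#' @param scores numeric vector, higher favoring the positive class.
#' @param truth class labels aligned with `scores`.
#' @param positiveClass the positive label.
#' @return List with `points` (data.frame fpr/tpr/threshold, monotone
#'   nondecreasing) and `auc`.
#' @export
rocFromScores <- function(scores, truth, positiveClass) {
  stopifnot(length(scores) == length(truth), all(is.finite(scores)))
  pos <- truth == positiveClass
  nP <- sum(pos); nN <- sum(!pos)
  if (nP == 0 || nN == 0) stop("both classes must be present")
  if (length(unique(scores)) == 1L)
    warning("constant scores: ROC is the chance diagonal (AUC 0.5)")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(vapply(thr, function(th) {
    called <- scores >= th
    c(fpr = sum(called & !pos) / nN, tpr = sum(called & pos) / nP)
  }, numeric(2)))
  auc <- sum(diff(pts[, "fpr"]) * (utils::head(pts[, "tpr"], -1) +
                                   utils::tail(pts[, "tpr"], -1)) / 2)
  list(points = data.frame(fpr = pts[, "fpr"], tpr = pts[, "tpr"],
                           threshold = thr), auc = auc)
}

#' Leave-one-out cross-validation of the PLS-LDA pipeline
#'
#' For every subject the full pipeline — optional data-driven region
#' selection, PRESS component selection, PLS and LDA — is refitted on the
#' remaining N-1 subjects and the held-out subject is predicted, so each
#' subject is predicted exactly once. The positive class is the more
#' impaired diagnosis of the pair. With `selection = "refit"` the top-k
#' region selection is recomputed inside every training fold (leakage-safe);
#' `"once"` selects on the full table a single time before the loop.
#'
#' @param table a [FeatureTable-class] restricted to two diagnoses.
#' @param aMax PRESS search limit (default `min(8, d, N-3)`).
#' @param autoscale autoscale features within each training fold.
#' @param priors LDA class priors ("equal"/"empirical").
#' @param selection `"none"` (default), `"refit"` or `"once"` data-driven
#'   region selection.
#' @param k regions kept when selection is active.
#' @return List: per-subject data.frame `predictions` (truth, predicted,
#'   score), `positiveClass`, metrics `accuracy`/`sensitivity`/
#'   `specificity`, confusion counts, `roc` and `auc`.
#' @export
loocv <- function(table, aMax = NULL, autoscale = FALSE, priors = "equal",
                  selection = c("none", "refit", "once"), k = 12) {
  selection <- match.arg(selection)
  dx <- diagnosis(table)
  classes <- sort(unique(dx))
  if (length(classes) != 2) stop("LOOCV needs exactly two diagnostic groups")
  if (min(table(dx)) < 2) stop("both classes need at least 2 subjects")
  n <- length(dx)
  if (n < 4) stop("at least 4 subjects are required")
  posClass <- positiveClassOf(dx)
  negClass <- setdiff(classes, posClass)
  classLabels <- c(negClass, posClass)  # positive class coded 1
  if (selection == "once")
    table <- subsetRegions(table, selectDataDriven(table, classes[1], classes[2], k = k))
  X <- featureMatrix(table)
  regions <- as.character(SummarizedExperiment::rowData(table)$region)
  pred <- character(n); score <- numeric(n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]; ytr <- dx[-i]
    if (length(unique(ytr)) < 2)
      stop(sprintf("fold %d lost a class from its training set", i))
    Xte <- X[i, , drop = FALSE]
    if (selection == "refit") {
      tr_tab <- FeatureTable(Xtr, diagnosis = ytr,
                             modality = modality(table),
                             source = featureSource(table), region = regions)
      keepReg <- selectDataDriven(tr_tab, classes[1], classes[2], k = k)
      keep <- regions %in% keepReg
      Xtr <- Xtr[, keep, drop = FALSE]; Xte <- Xte[, keep, drop = FALSE]
    }
    fit <- fitPlsLda(Xtr, ytr, aMax = aMax, autoscale = autoscale,
                     priors = priors, classLabels = classLabels)
    p <- predict(fit, Xte)
    pred[i] <- p$label; score[i] <- p$score
  }
  cm <- confusionMetrics(pred, dx, posClass)
  roc <- rocFromScores(score, dx, posClass)
  list(predictions = data.frame(subject = rownames(X), truth = dx,
                                predicted = pred, score = score),
       positiveClass = posClass,
       accuracy = cm$accuracy, sensitivity = cm$sensitivity,
       specificity = cm$specificity,
       tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
       roc = roc$points, auc = roc$auc)
}
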