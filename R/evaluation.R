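# Performance assessment: confusion-matrix metrics (Acc, Sp, Sn, MCC),
# repeated stratified k-fold cross-validation, self-consistency testing,
# and ROC analysis with vertical averaging across repeats.

#' Confusion counts from predicted and true labels
#'
#' @param predicted,truth Character vectors "positive"/"negative".
#' @return Named numeric vector `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  c(TP = sum(predicted == "positive" & truth == "positive"),
    FP = sum(predicted == "positive" & truth == "negative"),
    TN = sum(predicted == "negative" & truth == "negative"),
    FN = sum(predicted == "negative" & truth == "positive"))
}

#' Classification metrics from confusion counts
#'
#' Acc = (TP+TN)/total, Sn = TP/(TP+FN), Sp = TN/(TN+FP), and Matthew's
#' correlation coefficient
#' MCC = (TP TN - FN FP) / sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN)).
#' MCC is defined as 0 when its denominator vanishes (a degenerate
#' predictor or single-class truth).
#'
#' @param counts Named vector with `TP`, `FP`, `TN`, `FN`.
#' @return Named numeric vector `Acc`, `Sp`, `Sn`, `MCC`.
#' @export
confusion_metrics <- function(counts) {
  tp <- as.numeric(counts[["TP"]]); fp <- as.numeric(counts[["FP"]])
  tn <- as.numeric(counts[["TN"]]); fn <- as.numeric(counts[["FN"]])
  total <- tp + fp + tn + fn
  stopifnot(total > 0)
  den <- sqrt((tp + fn) * (tn + fp) * (tp + fp) * (tn + fn))
  c(Acc = (tp + tn) / total,
    Sp = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    Sn = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    MCC = if (den > 0) (tp * tn - fn * fp) / den else 0)
}

#' Stratified fold assignment
#'
#' Random fold labels 1..k, stratified by class so each fold carries its
#' share of the minority class.
#'
#' @param labels Class labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids, parallel to `labels`.
#' @export
stratified_folds <- function(labels, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k)
      stop("class '", cl, "' has fewer members (", length(idx),
           ") than folds (", k, "); use fewer folds")
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Repeated stratified k-fold cross-validation
#'
#' Partitions the data into stratified random folds, uses each fold once
#' as the test set, and averages the four metrics over folds and then over
#' repeats; per-repeat standard deviations are reported.
#'
#' @param x Feature matrix (raw; scaling is the builder's job).
#' @param labels "positive"/"negative" labels.
#' @param model_builder `function(x_train, labels_train)` returning an
#'   object whose `predict` method yields a data.frame with a `label`
#'   column (see [sumo_svm()]).
#' @param n_folds Number of folds.
#' @param repeats Number of repeated partitions (25 in the reference
#'   protocol).
#' @param threshold Decision threshold passed to predict.
#' @param seed Integer seed controlling all fold assignments.
#' @return List with `mean`, `sd` (named metric vectors) and `per_repeat`
#'   (data.frame of per-repeat fold-averaged metrics).
#' @export
cross_validate <- function(x, labels, model_builder, n_folds = 5,
                           repeats = 25, threshold = "medium", seed = 1) {
  stopifnot(n_folds >= 2, length(unique(labels)) == 2)
  per_repeat <- matrix(NA_real_, repeats, 4,
                       dimnames = list(NULL, c("Acc", "Sp", "Sn", "MCC")))
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(labels, n_folds, seed = seed + r - 1L)
    fold_metrics <- vapply(seq_len(n_folds), function(f) {
      tr <- fold != f
      model <- model_builder(x[tr, , drop = FALSE], labels[tr])
      pred <- predict(model, x[!tr, , drop = FALSE], threshold = threshold)
      confusion_metrics(confusion_counts(pred$label, labels[!tr]))
    }, numeric(4))
    per_repeat[r, ] <- rowMeans(fold_metrics)
  }
  list(mean = colMeans(per_repeat),
       sd = apply(per_repeat, 2, stats::sd),
       per_repeat = as.data.frame(per_repeat))
}

#' Self-consistency test
#'
#' Trains on the full dataset and evaluates on the same data, measuring
#' the model's fitting capacity rather than generalization.
#'
#' @inheritParams cross_validate
#' @return Named metric vector `Acc`, `Sp`, `Sn`, `MCC`.
#' @export
self_consistency <- function(x, labels, model_builder, threshold = "medium") {
  model <- model_builder(x, labels)
  pred <- predict(model, x, threshold = threshold)
  confusion_metrics(confusion_counts(pred$label, labels))
}

#' ROC curve and AUC from decision values
#'
#' Threshold-sweep ROC (ties grouped, so AUC equals the probability that a
#' positive scores above a negative, counting ties half), with trapezoidal
#' AUC.
#'
#' @param scores Numeric decision values (larger = more positive).
#' @param labels "positive"/"negative" labels.
#' @return List of class `sumo_roc` with `fpr`, `tpr`, `auc`.
#' @export
roc_curve <- function(scores, labels) {
  pos <- labels == "positive"
  if (!any(pos) || all(pos)) stop("ROC needs both classes")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # cut only between distinct score values
  keep <- c(s[-length(s)] != s[-1], TRUE)
  tpr <- c(0, cumsum(p)[keep] / sum(pos))
  fpr <- c(0, cumsum(!p)[keep] / sum(!pos))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(fpr = fpr, tpr = tpr, auc = auc), class = "sumo_roc")
}

#' Vertically averaged ROC curve over repeats
#'
#' Interpolates each repeat's TPR onto a fixed FPR grid, averages
#' vertically, and computes the AUC of the averaged curve.
#'
#' @param curves List of `sumo_roc` objects.
#' @param grid FPR grid (default 101 points on \[0,1\]).
#' @return `sumo_roc` with the averaged curve, its `auc`, and `per_curve_auc`.
#' @export
average_roc <- function(curves, grid = seq(0, 1, length.out = 101)) {
  tpr <- vapply(curves, function(cv)
    stats::approx(cv$fpr, cv$tpr, xout = grid, ties = max, rule = 2)$y,
    numeric(length(grid)))
  mtpr <- rowMeans(tpr)
  auc <- sum(diff(grid) * (utils::head(mtpr, -1) + utils::tail(mtpr, -1)) / 2)
  structure(list(fpr = grid, tpr = mtpr, auc = auc,
                 per_curve_auc = vapply(curves, `[[`, numeric(1), "auc")),
            class = "sumo_roc")
}

#' @export
print.sumo_roc <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC = %.3f\n", length(x$fpr), x$auc))
  invisible(x)
}

#' @export
plot.sumo_roc <- function(x, ...) {
  plot(x$fpr, x$tpr, type = "l", xlab = "False positive rate",
       ylab = "True positive rate",
       main = sprintf("ROC (AUC = %.2f)", x$auc), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

#' Metrics of the consensus-regex baseline
#'
#' Evaluates the motif scanner as a classifier: predict positive exactly
#' when the window matches the consensus motif.
#'
#' @param consensus Logical consensus status per site.
#' @param labels True labels.
#' @return Named metric vector `Acc`, `Sp`, `Sn`, `MCC`.
#' @export
regex_baseline_metrics <- function(consensus, labels) {
  confusion_metrics(confusion_counts(
    ifelse(consensus, "positive", "negative"), labels))
}

#' Side-by-side evaluation report
#'
#' Assembles a metrics table (rows = evaluation methods, columns Acc, Sp,
#' Sn, MCC) rounded to two decimals for reporting; full-precision values
#' are kept in the `full` attribute.
#'
#' @param ... Named metric vectors as produced by the evaluation
#'   functions.
#' @return data.frame report.
#' @export
metrics_report <- function(...) {
  rows <- list(...)
  full <- do.call(rbind, rows)
  out <- as.data.frame(round(full, 2))
  out <- cbind(method = names(rows), out)
  rownames(out) <- NULL
  attr(out, "full") <- full
  out
}
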