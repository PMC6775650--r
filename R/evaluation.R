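#' One-vs-all confusion counts
#'
#' Reduces a multi-class result to the 2x2 table of one class against the
#' rest: every metric of the package (accuracy, MCC, sensitivity,
#' specificity) is computed from these four counts.
#'
#' @param predictions,truths Equal-length label vectors.
#' @param positive_class The class counted as positive.
#' @return An object of class `drs_confusion` with fields `TP`, `FP`,
#'   `TN`, `FN`.
#' @export
confusion <- function(predictions, truths, positive_class) {
  if (length(predictions) != length(truths)) {
    stop("predictions and truths must have the same length", call. = FALSE)
  }
  if (length(predictions) == 0L) {
    stop("cannot build confusion counts from empty input", call. = FALSE)
  }
  p <- predictions == positive_class
  t <- truths == positive_class
  confusion_counts(TP = sum(p & t), FP = sum(p & !t),
                   TN = sum(!p & !t), FN = sum(!p & t))
}

#' @rdname confusion
#' @param TP,FP,TN,FN Non-negative integer counts (total > 0).
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  counts <- c(TP = unname(TP), FP = unname(FP), TN = unname(TN),
              FN = unname(FN))
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) == 0) stop("total count must be > 0", call. = FALSE)
  # doubles, not integers: denominator products overflow 32-bit range
  structure(as.list(stats::setNames(as.numeric(counts), names(counts))),
            class = "drs_confusion")
}

#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, the
#' balanced binary quality measure: +1 for perfect classification, 0 for
#' classification no better than chance, -1 for complete reversal. When any
#' factor of the denominator is zero the conventional value 0 is returned.
#' Equivalent to the Pearson correlation of the two binary label vectors.
#'
#' @param c A `drs_confusion`.
#' @return Value in `[-1, 1]`.
#' @examples
#' mcc(confusion_counts(TP = 2, FP = 13, TN = 39, FN = 0))  # ~0.316
#' @export
mcc <- function(c) {
  stopifnot(inherits(c, "drs_confusion"))
  denom <- (c$TP + c$FP) * (c$TP + c$FN) * (c$TN + c$FP) * (c$TN + c$FN)
  if (denom == 0) return(0)
  (c$TP * c$TN - c$FP * c$FN) / sqrt(denom)
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' Rates with an undefined denominator (no positives for sensitivity, no
#' negatives for specificity) are returned as `NA`, never silently as 0.
#'
#' @param c A `drs_confusion`.
#' @return Named list `accuracy`, `sensitivity`, `specificity`.
#' @export
basic_rates <- function(c) {
  stopifnot(inherits(c, "drs_confusion"))
  total <- c$TP + c$FP + c$TN + c$FN
  list(
    accuracy = (c$TP + c$TN) / total,
    sensitivity = if (c$TP + c$FN > 0) c$TP / (c$TP + c$FN) else NA_real_,
    specificity = if (c$TN + c$FP > 0) c$TN / (c$TN + c$FP) else NA_real_)
}

#' Count-weighted mean accuracy over classes
#'
#' The average accuracy over all tissue types weighted by the number of
#' measurements per tissue type: `sum(acc_i * n_i) / sum(n_i)`.
#'
#' @param per_class_accuracy Named numeric vector of per-class accuracies.
#' @param per_class_counts Named numeric vector of per-class measurement
#'   counts (> 0), same names.
#' @return A single weighted accuracy value.
#' @examples
#' weighted_accuracy(c(fat = 0.92, wall = 0.89, tumor = 0.94),
#'                   c(fat = 402, wall = 282, tumor = 87))  # 0.911
#' @export
weighted_accuracy <- function(per_class_accuracy, per_class_counts) {
  if (!setequal(names(per_class_accuracy), names(per_class_counts)) ||
      is.null(names(per_class_accuracy))) {
    stop("accuracies and counts must share the same class names",
         call. = FALSE)
  }
  n <- per_class_counts[names(per_class_accuracy)]
  if (any(n <= 0)) stop("counts must be > 0", call. = FALSE)
  sum(per_class_accuracy * n) / sum(n)
}

#' ROC curve and AUC from signed scores
#'
#' Sweeps the decision threshold over all distinct scores (with infinite
#' endpoints so the curve is anchored at (0,0) and (1,1)); an item is
#' called positive when its score strictly exceeds the threshold. AUC by
#' the trapezoid rule; equals the normalized Mann-Whitney rank statistic.
#'
#' @param scores Numeric scores, larger = more positive.
#' @param truths Logical (or 0/1) positive-class indicator.
#' @return List with `points` (data frame of threshold, fpr, tpr ordered
#'   from (0,0) to (1,1)) and `auc`.
#' @export
roc_curve <- function(scores, truths) {
  truths <- as.logical(truths)
  if (length(scores) != length(truths)) {
    stop("scores and truths must have the same length", call. = FALSE)
  }
  if (!any(truths) || all(truths)) {
    stop("both classes must be present for a ROC curve", call. = FALSE)
  }
  np <- sum(truths)
  nn <- sum(!truths)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) sum(scores[truths] > t) / np, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores[!truths] > t) / nn, numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}

# One-vs-all score of each class for ROC purposes. Fat: stage-one score.
# Tumor: stage-two score (stage two evaluated for every spectrum). Wall:
# a spectrum looks like wall when it is on neither the fat nor the tumor
# side, so its score is the smaller of the two negated stage scores.
class_score <- function(predictions, class) {
  switch(class,
         fat = predictions$score_fat,
         tumor = predictions$score_tumor,
         wall = pmin(-predictions$score_fat, -predictions$score_tumor))
}

#' Full metrics report from cross-validation predictions
#'
#' For each tissue class and each repeat, the one-vs-all confusion counts
#' give accuracy, MCC, sensitivity and specificity; the report carries
#' their mean and standard deviation across repeats, the count-weighted
#' mean accuracy, and a ROC curve per class from one repeat's scores.
#' Metrics are computed per measurement (`level = "measurement"`) or per
#' location after majority voting (`level = "location"`).
#'
#' @param predictions Prediction records from [cross_validate()] (with
#'   stage-two scores kept for all spectra).
#' @param level `"measurement"` or `"location"`.
#' @param roc_repeat Which repeat's scores feed the ROC curves (default 1).
#' @return An object of class `drs_metrics_report`: `per_class` data frame
#'   (class, metric means and SDs, n), `weighted_accuracy`, `roc` (named
#'   list of [roc_curve()] results), `level`.
#' @export
metrics_report <- function(predictions, level = c("measurement", "location"),
                           roc_repeat = 1L) {
  level <- match.arg(level)
  if (level == "location") predictions <- aggregate_locations(predictions)
  classes <- sort(unique(predictions$true_class))
  reps <- sort(unique(predictions$repeat_index))
  per_rep <- expand.grid(class = classes, repeat_index = reps,
                         stringsAsFactors = FALSE)
  vals <- lapply(seq_len(nrow(per_rep)), function(i) {
    d <- predictions[predictions$repeat_index == per_rep$repeat_index[i], ]
    cc <- confusion(d$predicted_class, d$true_class, per_rep$class[i])
    c(list(mcc = mcc(cc)), basic_rates(cc))
  })
  per_rep$accuracy <- vapply(vals, `[[`, numeric(1), "accuracy")
  per_rep$mcc <- vapply(vals, `[[`, numeric(1), "mcc")
  per_rep$sensitivity <- vapply(vals, `[[`, numeric(1), "sensitivity")
  per_rep$specificity <- vapply(vals, `[[`, numeric(1), "specificity")

  agg <- function(metric, f) {
    vapply(classes, function(cl)
      f(per_rep[per_rep$class == cl, metric]), numeric(1))
  }
  per_class <- data.frame(
    class = classes,
    n = vapply(classes, function(cl)
      sum(predictions$true_class == cl &
            predictions$repeat_index == reps[1]), numeric(1)),
    accuracy_mean = agg("accuracy", mean), accuracy_sd = agg("accuracy", sd),
    mcc_mean = agg("mcc", mean), mcc_sd = agg("mcc", sd),
    sensitivity_mean = agg("sensitivity", mean),
    sensitivity_sd = agg("sensitivity", sd),
    specificity_mean = agg("specificity", mean),
    specificity_sd = agg("specificity", sd),
    stringsAsFactors = FALSE)
  rownames(per_class) <- NULL
  wacc <- weighted_accuracy(
    stats::setNames(per_class$accuracy_mean, per_class$class),
    stats::setNames(per_class$n, per_class$class))
  d1 <- predictions[predictions$repeat_index == roc_repeat, ]
  roc <- lapply(stats::setNames(nm = classes), function(cl)
    roc_curve(class_score(d1, cl), d1$true_class == cl))
  structure(list(per_class = per_class, per_repeat = per_rep,
                 weighted_accuracy = wacc, roc = roc, level = level),
            class = "drs_metrics_report")
}

#' @export
print.drs_metrics_report <- function(x, ...) {
  cat(sprintf("<drs_metrics_report> per %s, %d repeats\n", x$level,
              length(unique(x$per_repeat$repeat_index))))
  pc <- x$per_class
  for (i in seq_len(nrow(pc))) {
    cat(sprintf(
      "  %-6s acc %.2f (%.2f)  MCC %.2f (%.2f)  sens %.2f (%.2f)  spec %.2f (%.2f)\n",
      pc$class[i], pc$accuracy_mean[i], pc$accuracy_sd[i],
      pc$mcc_mean[i], pc$mcc_sd[i], pc$sensitivity_mean[i],
      pc$sensitivity_sd[i], pc$specificity_mean[i], pc$specificity_sd[i]))
  }
  cat(sprintf("  weighted accuracy %.2f\n", x$weighted_accuracy))
  invisible(x)
}
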