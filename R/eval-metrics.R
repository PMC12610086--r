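# Detection/segmentation evaluation metrics and hard-negative confusion
# aggregation.

#' Confusion counts for one hard-negative class
#'
#' Holds TP/FP/TN/FN counts of a detector evaluated against one negative
#' object class (e.g. ink, anthracosis, muscle/fibroblast nuclei, necrotic
#' chromatin) or a combined row.
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @param negative_class Label of the negative class (default `"combined"`).
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, tn, fn, negative_class = "combined") {
  cnt <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(!is.finite(cnt)) || any(cnt < 0) || any(cnt != round(cnt)))
    stop("counts must be non-negative integers", call. = FALSE)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 tn = as.integer(tn), fn = as.integer(fn),
                 negative_class = as.character(negative_class)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> %s: TP %d FP %d TN %d FN %d\n",
              x$negative_class, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Sensitivity, specificity, precision and F1 from confusion counts
#'
#' @param c A [confusion_counts()] object.
#' @return Named list with `sensitivity` = TP/(TP+FN), `specificity` =
#'   TN/(TN+FP), `precision` = TP/(TP+FP) and `f1` (harmonic mean of
#'   precision and sensitivity). A zero denominator raises an error naming
#'   the metric.
#' @export
confusion_metrics <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  den <- function(v, metric) {
    if (v == 0) stop("undefined metric: ", metric, " (zero denominator)",
                     call. = FALSE)
    v
  }
  sens <- c$tp / den(c$tp + c$fn, "sensitivity")
  spec <- c$tn / den(c$tn + c$fp, "specificity")
  prec <- c$tp / den(c$tp + c$fp, "precision")
  list(sensitivity = sens, specificity = spec, precision = prec,
       f1 = f1_from_pr(prec, sens))
}

#' F1 score from precision and recall
#'
#' @param precision,recall Values in `[0, 1]` with a positive sum.
#' @return Harmonic mean `2 * precision * recall / (precision + recall)`.
#' @export
#' @examples
#' f1_from_pr(0.89, 0.83)
f1_from_pr <- function(precision, recall) {
  if (precision + recall <= 0)
    stop("precision + recall must be positive", call. = FALSE)
  2 * precision * recall / (precision + recall)
}

#' Combine per-negative-class confusion rows
#'
#' Hard-negative evaluations share the positive set, so TP and FN are
#' identical across rows; FPs and TNs accumulate over the negative classes.
#'
#' @param rows List of [confusion_counts()] sharing `tp` and `fn`.
#' @return A combined [confusion_counts()].
#' @export
combine_negative_classes <- function(rows) {
  if (!length(rows)) stop("no rows to combine", call. = FALSE)
  for (r in rows) stopifnot(inherits(r, "confusion_counts"))
  tps <- vapply(rows, `[[`, integer(1), "tp")
  fns <- vapply(rows, `[[`, integer(1), "fn")
  if (length(unique(tps)) != 1L || length(unique(fns)) != 1L)
    stop("rows disagree on tp/fn: not the same positive set", call. = FALSE)
  confusion_counts(tps[1],
                   sum(vapply(rows, `[[`, integer(1), "fp")),
                   sum(vapply(rows, `[[`, integer(1), "tn")),
                   fns[1],
                   paste(vapply(rows, `[[`, character(1), "negative_class"),
                         collapse = " + "))
}

#' IoU and Dice overlap of two boolean masks
#'
#' Used e.g. for interobserver agreement of segmentation masks. Two empty
#' masks are defined as perfect agreement (both metrics 1).
#'
#' @param mask_a,mask_b Logical arrays of identical shape.
#' @return Named vector `c(iou, dice)`.
#' @export
overlap_metrics <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)) || length(mask_a) != length(mask_b))
    stop("mask shapes differ", call. = FALSE)
  a <- as.logical(mask_a); b <- as.logical(mask_b)
  inter <- sum(a & b); uni <- sum(a | b)
  if (uni == 0) return(c(iou = 1, dice = 1))
  c(iou = inter / uni, dice = 2 * inter / (sum(a) + sum(b)))
}

#' Area under the ROC curve
#'
#' Trapezoidal AUC with tied scores averaged (equivalent to the Mann-Whitney
#' rank statistic), computed via pROC.
#'
#' @param scores Numeric detection scores.
#' @param labels Logical (or 0/1) ground-truth labels; both classes must be
#'   present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L)
    stop("both label classes must be present", call. = FALSE)
  as.numeric(pROC::auc(pROC::roc(response = labels, predictor = scores,
                                 levels = c(FALSE, TRUE), direction = "<",
                                 quiet = TRUE)))
}

#' Two-stage detection/classification threshold sweep
#'
#' Emulates a detector with a second-stage classifier: candidates whose
#' detection score reaches `detection_thr` pass to stage two; a candidate is
#' called positive iff it also reaches `classification_thr`. Positives and
#' negatives are then counted against the labels.
#'
#' @param detection_scores,classification_scores Numeric vectors in `[0, 1]`,
#'   one entry per candidate.
#' @param labels Logical ground truth per candidate.
#' @param detection_thr,classification_thr Stage thresholds in `[0, 1]`
#'   (defaults 0.3 and 0.65).
#' @param negative_class Label carried on the result.
#' @return A [confusion_counts()] object.
#' @export
threshold_sweep <- function(detection_scores, classification_scores, labels,
                            detection_thr = 0.3, classification_thr = 0.65,
                            negative_class = "combined") {
  stopifnot(length(detection_scores) == length(labels),
            length(classification_scores) == length(labels))
  if (detection_thr < 0 || detection_thr > 1 ||
      classification_thr < 0 || classification_thr > 1)
    stop("thresholds must lie in [0, 1]", call. = FALSE)
  labels <- as.logical(labels)
  called <- detection_scores >= detection_thr &
    classification_scores >= classification_thr
  confusion_counts(sum(called & labels), sum(called & !labels),
                   sum(!called & !labels), sum(!called & labels),
                   negative_class)
}

#' Read or write confusion tables as CSV
#'
#' Columns: `negative_class`, `tp`, `fp`, `tn`, `fn`.
#'
#' @param path CSV file path.
#' @return `read_confusion_csv()` returns a list of [confusion_counts()];
#'   `write_confusion_csv()` returns `path` invisibly.
#' @export
read_confusion_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(d)), function(i)
    confusion_counts(d$tp[i], d$fp[i], d$tn[i], d$fn[i], d$negative_class[i]))
}

#' @param rows List of [confusion_counts()].
#' @rdname read_confusion_csv
#' @export
write_confusion_csv <- function(rows, path) {
  d <- do.call(rbind, lapply(rows, function(r)
    data.frame(negative_class = r$negative_class, tp = r$tp, fp = r$fp,
               tn = r$tn, fn = r$fn, stringsAsFactors = FALSE)))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

# Report-display rounding: half-up to 2 decimals (tables mix conventions;
# raw values are kept internally).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
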