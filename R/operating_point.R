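# Operating-point selection on the PR curve and the confusion-matrix metric
# family (F1, accuracy, precision, recall, specificity), per class and for
# the binary FOG-vs-non-FOG case.

#' Select the PR-optimal decision threshold
#'
#' Returns the threshold of the precision-recall point minimizing the
#' Euclidean distance to (1, 1), i.e. perfect precision and recall. Ties are
#' broken toward higher recall, then toward the lower threshold — the
#' clinically conservative direction (a missed freeze costs more than a
#' false alarm).
#'
#' @param curve a `fog_pr_curve` from [pr_curve].
#' @return the selected threshold.
#' @export
select_threshold <- function(curve) {
  if (!nrow(curve)) stop_argument("empty PR curve")
  d2 <- (1 - curve$precision)^2 + (1 - curve$recall)^2
  best <- d2 <= min(d2) + 1e-12
  cand <- curve[best, , drop = FALSE]
  cand <- cand[cand$recall >= max(cand$recall) - 1e-12, , drop = FALSE]
  min(cand$threshold)
}

#' Collapse class labels and scores to the binary FOG-vs-non-FOG problem
#'
#' The binary label is the OR over the three class channels and `notype`;
#' the binary score is the per-sample maximum over the three class
#' confidences (a sample is as suspicious as its most confident class).
#'
#' @param labels a [fog_labels].
#' @param scores score matrix aligned to `labels`.
#' @return list(`labels` logical, `scores` numeric).
#' @export
binarize_all_fog <- function(labels, scores) {
  scores <- fog_scores(scores)
  if (nrow(scores) != labels$n)
    stop_alignment("labels and scores differ in length")
  list(labels = any_fog(labels),
       scores = pmax(scores[, 1], scores[, 2], scores[, 3]))
}

#' Confusion-matrix metrics of binary decisions
#'
#' Computed from the masked 2x2 table. Precision (and F1) are `NA` with
#' `precision_defined = FALSE` when there are no positive decisions; such
#' rows are excluded from aggregates rather than counted as zero.
#'
#' @param labels binary ground truth.
#' @param decisions binary decisions.
#' @param mask optional logical evaluation mask.
#' @return one-row data.frame with tp/fp/fn/tn and the metric family.
#' @export
confusion_metrics <- function(labels, decisions, mask = NULL) {
  labels <- as.logical(labels); decisions <- as.logical(decisions)
  if (length(labels) != length(decisions))
    stop_alignment("labels and decisions differ in length")
  labels <- apply_mask(labels, mask); decisions <- apply_mask(decisions, mask)
  tp <- sum(labels & decisions); fp <- sum(!labels & decisions)
  fn <- sum(labels & !decisions); tn <- sum(!labels & !decisions)
  precision_defined <- (tp + fp) > 0
  precision <- if (precision_defined) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  specificity <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  f1 <- if (precision_defined && !is.na(recall) && (precision + recall) > 0)
    2 * precision * recall / (precision + recall)
  else if (precision_defined && !is.na(recall)) 0 else NA_real_
  data.frame(tp = tp, fp = fp, fn = fn, tn = tn,
             f1 = f1, accuracy = (tp + tn) / (tp + fp + fn + tn),
             precision = precision, recall = recall,
             specificity = specificity,
             precision_defined = precision_defined)
}

#' Operating-point metric table per class and for all-FOG
#'
#' For each of the three FOG classes and for the binary all-FOG case, a
#' decision threshold is selected independently on that problem's PR curve
#' (nearest (1,1); see [select_threshold]) and the confusion-matrix metrics
#' are reported at it. Per-class rows exclude `notype` samples (class
#' unknown); the all-FOG row counts them as positives.
#'
#' @param labels a [fog_labels].
#' @param scores aligned score matrix.
#' @param mask optional logical mask; defaults to Valid-and-Task.
#' @return data.frame, one row per class plus `all_fog`.
#' @export
operating_point_metrics <- function(labels, scores, mask = NULL) {
  scores <- fog_scores(scores)
  if (is.null(mask)) mask <- make_mask(labels)
  rows <- lapply(FOG_CLASSES, function(cl) {
    m <- mask & !labels$notype
    curve <- pr_curve(labels[[cl]], scores[, cl], m)
    thr <- select_threshold(curve)
    cbind(data.frame(fog_class = cl, threshold = thr),
          confusion_metrics(labels[[cl]], scores[, cl] >= thr, m))
  })
  bin <- binarize_all_fog(labels, scores)
  curve <- pr_curve(bin$labels, bin$scores, mask)
  thr <- select_threshold(curve)
  rows <- c(rows, list(cbind(data.frame(fog_class = "all_fog", threshold = thr),
                             confusion_metrics(bin$labels, bin$scores >= thr, mask))))
  do.call(rbind, rows)
}
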