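# Competition scoring: per-class average precision over masked per-sample
# confidences, mean-averaged across the three FOG classes; PR/ROC curves.

# shared ranking kernel: per descending unique threshold, cumulative TP/FP
rank_counts <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # last index of each tie group = counts at that threshold
  grp_end <- which(!duplicated(s, fromLast = TRUE))
  list(threshold = s[grp_end],
       tp = cumsum(y)[grp_end],
       fp = cumsum(!y)[grp_end])
}

apply_mask <- function(x, mask) if (is.null(mask)) x else x[as.logical(mask)]

#' Non-interpolated average precision
#'
#' The per-class sample-level metric: with thresholds swept over the unique
#' confidence values in descending order, AP = sum over thresholds of
#' (R_n - R_(n-1)) * P_n, computed only on masked samples. Tied scores share
#' one threshold. Undefined metrics raise a classed error rather than
#' defaulting to zero.
#'
#' @param labels binary ground-truth vector.
#' @param scores real confidence vector, higher = more confident.
#' @param mask optional logical evaluation mask.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(labels, scores, mask = NULL) {
  labels <- as.logical(apply_mask(labels, mask))
  scores <- apply_mask(scores, mask)
  if (length(labels) != length(scores))
    stop_alignment("labels and scores differ in length")
  npos <- sum(labels)
  if (npos == 0L)
    stop_undefined_metric("average precision undefined: no positive samples in mask")
  rc <- rank_counts(labels, scores)
  recall <- rc$tp / npos
  precision <- rc$tp / (rc$tp + rc$fp)
  sum(diff(c(0, recall)) * precision)
}

#' Precision-recall curve
#'
#' One point per unique threshold (descending), preceded by the conventional
#' `(recall 0, precision 1)` anchor at threshold `Inf`.
#'
#' @inheritParams average_precision
#' @return data.frame (`threshold`, `precision`, `recall`) of class
#'   `fog_pr_curve`.
#' @export
pr_curve <- function(labels, scores, mask = NULL) {
  labels <- as.logical(apply_mask(labels, mask))
  scores <- apply_mask(scores, mask)
  npos <- sum(labels)
  if (npos == 0L) stop_undefined_metric("PR curve undefined: no positives in mask")
  rc <- rank_counts(labels, scores)
  out <- data.frame(threshold = c(Inf, rc$threshold),
                    precision = c(1, rc$tp / (rc$tp + rc$fp)),
                    recall = c(0, rc$tp / npos))
  class(out) <- c("fog_pr_curve", "data.frame")
  out
}

#' ROC curve and trapezoidal AUC
#'
#' @inheritParams average_precision
#' @return data.frame (`threshold`, `fpr`, `tpr`) of class `fog_roc_curve`
#'   with attribute `auc`.
#' @export
roc_curve <- function(labels, scores, mask = NULL) {
  labels <- as.logical(apply_mask(labels, mask))
  scores <- apply_mask(scores, mask)
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0L || nneg == 0L)
    stop_undefined_metric("ROC undefined: need at least one positive and one negative")
  rc <- rank_counts(labels, scores)
  out <- data.frame(threshold = c(Inf, rc$threshold),
                    fpr = c(0, rc$fp / nneg),
                    tpr = c(0, rc$tp / npos))
  auc <- sum(diff(out$fpr) * (head(out$tpr, -1) + tail(out$tpr, -1)) / 2)
  class(out) <- c("fog_roc_curve", "data.frame")
  attr(out, "auc") <- auc
  out
}

#' @rdname roc_curve
#' @param curve a `fog_roc_curve`.
#' @export
auc <- function(curve) attr(curve, "auc")

#' Mean average precision across the three FOG classes
#'
#' Samples are pooled across sessions per class (micro-averaging, as a single
#' pooled submission was scored); `notype` samples — FOG of unknown class —
#' are excluded from all three per-class computations; samples outside the
#' Valid-and-Task mask are excluded throughout. Returns the unweighted mean
#' of the three class APs.
#'
#' @param labels_list list of [fog_labels], one per session.
#' @param scores_list list of score matrices (see [fog_scores]), aligned.
#' @param masks_list optional list of logical masks; defaults to each
#'   session's Valid-and-Task mask.
#' @return list with `per_class` (named APs) and `mAP`.
#' @export
mean_average_precision <- function(labels_list, scores_list, masks_list = NULL) {
  if (length(labels_list) != length(scores_list))
    stop_alignment("labels_list and scores_list differ in length")
  if (is.null(masks_list)) masks_list <- lapply(labels_list, make_mask)
  pooled_mask <- list()
  for (i in seq_along(labels_list)) {
    lb <- labels_list[[i]]
    if (nrow(scores_list[[i]]) != lb$n)
      stop_alignment(sprintf("session %d: scores and labels differ in length", i))
    pooled_mask[[i]] <- as.logical(masks_list[[i]]) & !lb$notype
  }
  per_class <- vapply(FOG_CLASSES, function(cl) {
    y <- unlist(lapply(labels_list, `[[`, cl), use.names = FALSE)
    s <- unlist(lapply(scores_list, function(m) m[, cl]), use.names = FALSE)
    m <- unlist(pooled_mask, use.names = FALSE)
    if (!any(y & m))
      stop_undefined_metric(paste0("no masked positives pooled for class ", cl))
    average_precision(y, s, m)
  }, numeric(1))
  list(per_class = per_class, mAP = mean(per_class))
}
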