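# Episode extraction from per-sample indicators and the three gold-standard
# outcomes: percent time frozen, episode count, total FOG duration.

#' Extract contiguous episodes from a binary series
#'
#' Maximal runs of true samples become episodes (0-based, half-open sample
#' intervals). Runs separated by gaps no longer than `merge_gap_s` are merged
#' first; episodes shorter than `min_duration_s` are then dropped. Both
#' post-processing knobs default to off, matching the headline analyses
#' which were run without event post-processing.
#'
#' @param x binary per-sample series.
#' @param sampling_rate Hz.
#' @param min_duration_s drop episodes strictly shorter than this.
#' @param merge_gap_s merge runs separated by gaps of at most this duration.
#' @param fog_class class tag stored on the episodes (default `"any"`).
#' @return data.frame (`fog_class`, `start`, `end`, `duration_s`), sorted and
#'   non-overlapping.
#' @export
extract_episodes <- function(x, sampling_rate, min_duration_s = 0,
                             merge_gap_s = 0, fog_class = "any") {
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop_validation("sampling_rate must be positive")
  x <- as.logical(x)
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths          # 0-based starts
  on <- r$values
  ep_start <- starts[on]; ep_end <- ends[on]
  if (length(ep_start) && merge_gap_s > 0) {
    gap_max <- merge_gap_s * sampling_rate + 1e-9
    keep_start <- ep_start[1]; out_s <- c(); out_e <- c()
    cur_end <- ep_end[1]
    for (i in seq_along(ep_start)[-1]) {
      if ((ep_start[i] - cur_end) <= gap_max) {
        cur_end <- ep_end[i]
      } else {
        out_s <- c(out_s, keep_start); out_e <- c(out_e, cur_end)
        keep_start <- ep_start[i]; cur_end <- ep_end[i]
      }
    }
    out_s <- c(out_s, keep_start); out_e <- c(out_e, cur_end)
    ep_start <- out_s; ep_end <- out_e
  }
  dur <- (ep_end - ep_start) / sampling_rate
  keep <- dur >= min_duration_s - 1e-12
  data.frame(fog_class = rep(fog_class, sum(keep)),
             start = ep_start[keep], end = ep_end[keep],
             duration_s = dur[keep])
}

#' Per-subject gold-standard outcomes
#'
#' Percent time frozen, episode count and total FOG duration, all restricted
#' to the evaluation mask: %TF = 100 * masked FOG time / masked observation
#' time. Episodes that do not intersect the mask do not contribute to either
#' the duration or the count.
#'
#' @param episodes episode table from [extract_episodes].
#' @param mask logical evaluation mask (length N).
#' @param sampling_rate Hz.
#' @param subject_id identifier carried into the result.
#' @return one-row data.frame (`subject_id`, `percent_time_frozen`,
#'   `n_episodes`, `total_duration_s`).
#' @export
subject_summary <- function(episodes, mask, sampling_rate, subject_id = "s01") {
  mask <- as.logical(mask)
  n <- length(mask)
  if (nrow(episodes) && (min(episodes$start) < 0 || max(episodes$end) > n))
    stop_validation("episodes extend outside the series")
  masked_samples <- sum(mask)
  if (masked_samples == 0L)
    stop_undefined_metric("%TF undefined: zero masked observation time")
  fog_samples <- 0L; n_ep <- 0L
  for (i in seq_len(nrow(episodes))) {
    hit <- sum(mask[(episodes$start[i] + 1L):episodes$end[i]])
    fog_samples <- fog_samples + hit
    if (hit > 0L) n_ep <- n_ep + 1L
  }
  data.frame(subject_id = subject_id,
             percent_time_frozen = 100 * fog_samples / masked_samples,
             n_episodes = n_ep,
             total_duration_s = fog_samples / sampling_rate)
}

#' Share of FOG time per class
#'
#' share_c = 100 * FOG time of class c / total FOG time. Input decisions must
#' be mutually exclusive per sample (when derived from model scores, resolve
#' multi-positive samples by score argmax first; see
#' [operating_point_metrics] thresholds).
#'
#' @param class_matrix logical N x 3 matrix, columns in canonical class
#'   order, at most one true per row.
#' @return named numeric vector of percentages summing to 100, or all-`NA`
#'   (flagged via attribute `defined = FALSE`) when no FOG time is present.
#' @export
class_time_shares <- function(class_matrix) {
  class_matrix <- as.matrix(class_matrix)
  if (ncol(class_matrix) != 3L) stop_validation("need 3 class columns")
  storage.mode(class_matrix) <- "logical"
  if (any(rowSums(class_matrix) > 1L))
    stop_validation("class decisions must be mutually exclusive per sample")
  tot <- sum(class_matrix)
  if (tot == 0L) {
    out <- setNames(rep(NA_real_, 3), FOG_CLASSES)
    attr(out, "defined") <- FALSE
    return(out)
  }
  out <- setNames(100 * colSums(class_matrix) / tot, FOG_CLASSES)
  attr(out, "defined") <- TRUE
  out
}

#' Aggregate a per-class, per-split event table
#'
#' Takes a long table of event counts and durations per FOG class and
#' dataset split and returns the class margins, the split margins and the
#' grand totals — the arithmetic of a dataset summary table.
#'
#' @param events long data.frame with columns `fog_class`, `split`,
#'   `events`, `duration_min`.
#' @return list(`by_class`, `by_split`, `total_events`,
#'   `total_duration_min`).
#' @export
dataset_summary <- function(events) {
  need <- c("fog_class", "split", "events", "duration_min")
  missing <- setdiff(need, names(events))
  if (length(missing))
    stop_schema(paste0("event table missing column(s): ",
                       paste(missing, collapse = ", ")))
  if (any(events$events < 0) || any(events$duration_min < 0))
    stop_validation("negative entries in event table")
  agg <- function(key) {
    e <- tapply(events$events, events[[key]], sum)
    d <- tapply(events$duration_min, events[[key]], sum)
    data.frame(key = names(e), events = as.vector(e),
               duration_min = as.vector(d), row.names = NULL)
  }
  by_class <- agg("fog_class"); names(by_class)[1] <- "fog_class"
  by_split <- agg("split"); names(by_split)[1] <- "split"
  list(by_class = by_class, by_split = by_split,
       total_events = sum(events$events),
       total_duration_min = sum(events$duration_min))
}
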