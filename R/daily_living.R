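# The 24/7 daily-living pipeline: padded walking-bout masks, OR ensembling,
# hourly/daily percent time frozen by clock hour, the night reference, and
# the non-parametric group comparisons.

#' Expand walking bouts into a padded evaluation mask
#'
#' FOG is assumed to occur only during or immediately around gait, so
#' daily-living evaluation is restricted to walking bouts padded by `pad_s`
#' seconds on each side (default 5 s). Overlapping padded bouts merge;
#' intervals are clipped to `[0, n)`.
#'
#' @param bouts data.frame with `start`, `end` (0-based half-open sample
#'   intervals), non-overlapping and sorted.
#' @param pad_s padding in seconds on each side.
#' @param n series length.
#' @param sampling_rate Hz.
#' @return logical vector of length `n`.
#' @export
expand_bouts <- function(bouts, pad_s = 5, n, sampling_rate) {
  mask <- logical(n)
  if (is.null(bouts) || nrow(bouts) == 0L) return(mask)
  pad <- round(pad_s * sampling_rate)
  s <- pmax(0L, as.integer(bouts$start) - pad)
  e <- pmin(n, as.integer(bouts$end) + pad)
  for (i in seq_along(s)) if (e[i] > s[i]) mask[(s[i] + 1L):e[i]] <- TRUE
  mask
}

#' Pointwise OR ensemble of binary decision series
#'
#' The daily-living joint model flags FOG wherever at least one member
#' detector does.
#'
#' @param decisions list of equal-length binary vectors.
#' @return logical vector.
#' @export
ensemble_or <- function(decisions) {
  if (!length(decisions)) stop_argument("need at least one decision series")
  n <- length(decisions[[1]])
  for (d in decisions) if (length(d) != n)
    stop_alignment("decision series differ in length")
  Reduce(`|`, lapply(decisions, as.logical))
}

# per-sample (day index, hour-of-day) attribution by sample midpoint,
# relative to the local midnight preceding start_clock
clock_bins <- function(start_clock, n, sampling_rate) {
  lt <- as.POSIXlt(start_clock)
  off0 <- lt$hour * 3600 + lt$min * 60 + lt$sec
  s <- off0 + (seq_len(n) - 0.5) / sampling_rate
  hour_abs <- floor(s / 3600)
  list(day = hour_abs %/% 24L, hour = hour_abs %% 24L)
}

#' Hourly percent time frozen restricted to walking-bout time
#'
#' For every day and clock hour, %TF = 100 * (FOG-and-mask seconds) /
#' (mask seconds in that hour); a bin is undefined (NA) when the hour
#' contains no bout time. The week-averaged 24-vector averages each hour
#' over the days where it is defined. Samples are attributed to bins by
#' their midpoint, so episodes spanning a bin edge split pro-rata at sample
#' resolution.
#'
#' @param decisions binary FOG decision series.
#' @param mask padded-bout evaluation mask (see [expand_bouts]).
#' @param start_clock `POSIXct` wall-clock time of the first sample.
#' @param sampling_rate Hz.
#' @param subject_id identifier carried into the profile.
#' @return object of class `fog_hourly_profile`: per-day matrices `tf` and
#'   `bout_seconds` (days x 24), week-averaged `week_avg`, per-day `daily`
#'   %TF and `daily_bout_seconds`.
#' @export
hourly_tf <- function(decisions, mask, start_clock, sampling_rate,
                      subject_id = "s01") {
  decisions <- as.logical(decisions); mask <- as.logical(mask)
  n <- length(decisions)
  if (length(mask) != n) stop_alignment("decisions and mask differ in length")
  if (is.null(start_clock)) stop_argument("start_clock is required")
  bins <- clock_bins(start_clock, n, sampling_rate)
  n_days <- max(bins$day) + 1L
  nb <- n_days * 24L
  bin <- bins$day * 24L + bins$hour
  bout_n <- tabulate(bin[mask] + 1L, nbins = nb)
  fog_n <- tabulate(bin[mask & decisions] + 1L, nbins = nb)
  bout_sec <- matrix(bout_n / sampling_rate, nrow = n_days, ncol = 24L, byrow = TRUE)
  fog_sec <- matrix(fog_n / sampling_rate, nrow = n_days, ncol = 24L, byrow = TRUE)
  tf <- 100 * fog_sec / bout_sec
  tf[bout_sec == 0] <- NA_real_
  week_avg <- colMeans(tf, na.rm = TRUE)
  week_avg[!is.finite(week_avg)] <- NA_real_
  daily_bout <- rowSums(bout_sec)
  daily <- 100 * rowSums(fog_sec) / daily_bout
  daily[daily_bout == 0] <- NA_real_
  structure(list(subject_id = subject_id, tf = tf, bout_seconds = bout_sec,
                 week_avg = week_avg, daily = daily,
                 daily_bout_seconds = daily_bout),
            class = "fog_hourly_profile")
}

#' Daily percent time frozen
#'
#' 100 * (daily FOG-and-mask time) / (daily bout time), with days bounded at
#' local midnight. Equals the bout-time-weighted mean of that day's defined
#' hourly values.
#'
#' @inheritParams hourly_tf
#' @return numeric vector, one %TF per day (NA for days without bout time).
#' @export
daily_tf <- function(decisions, mask, start_clock, sampling_rate) {
  hourly_tf(decisions, mask, start_clock, sampling_rate)$daily
}

#' Night-time reference percent time frozen
#'
#' Median of the defined week-averaged hourly %TF bins over the configured
#' night hours (default 23:00-06:59, the complement of the 07:00-22:59
#' daytime window). Used as the per-subject reference level that daytime
#' hours are compared against.
#'
#' @param profile a `fog_hourly_profile` (or a 24-vector of week-averaged
#'   hourly %TF).
#' @param night_hours integer clock hours making up the night window.
#' @return the median, or `NA` (with a warning) when no night bin is
#'   defined — such subjects are excluded from the daytime-vs-night
#'   comparison.
#' @export
night_reference <- function(profile, night_hours = c(23, 0:6)) {
  week <- if (inherits(profile, "fog_hourly_profile")) profile$week_avg else profile
  vals <- week[night_hours + 1L]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) {
    warning("no defined night bins; subject excluded from night-referenced comparisons")
    return(NA_real_)
  }
  median(vals)
}

# friedman.test returns NaN when every block is fully tied (zero rank
# variability); that degenerate table carries no evidence of a difference
friedman_safe <- function(X) {
  r <- friedman.test(X)
  if (!is.finite(r$statistic)) {
    r$statistic[] <- 0
    r$p.value <- 1
  }
  r
}

profiles_to_matrix <- function(profiles) {
  if (is.matrix(profiles)) return(profiles)
  do.call(rbind, lapply(profiles, function(p)
    if (inherits(p, "fog_hourly_profile")) p$week_avg else as.numeric(p)))
}

mw_test_p <- function(a, b) {
  # exact enumeration for small tie-free samples, tie-corrected normal
  # approximation otherwise (wilcox.test's default policy)
  if (length(unique(c(a, b))) == 1L) return(1)
  suppressWarnings(wilcox.test(a, b, alternative = "two.sided")$p.value)
}

#' Per-hour Mann-Whitney comparison of two groups' hourly %TF
#'
#' For each clock hour, the subjects' week-averaged hourly %TF values are
#' compared between groups with a two-tailed Mann-Whitney U test; the
#' per-hour p-values are then adjusted with the two-stage BKY FDR procedure
#' across the tested hours. Hours where either group has fewer than two
#' subjects with a defined bin are skipped and reported as such.
#'
#' @param profiles_a,profiles_b lists of `fog_hourly_profile` (or
#'   subjects x 24 matrices of week-averaged %TF).
#' @param hours clock hours to test (default all 24).
#' @param q FDR level.
#' @return data.frame per hour: group sizes, medians, `p`, `p_adj`,
#'   `significant`, `skipped`.
#' @export
compare_groups_hourly <- function(profiles_a, profiles_b, hours = 0:23,
                                  q = 0.05) {
  A <- profiles_to_matrix(profiles_a)
  B <- profiles_to_matrix(profiles_b)
  res <- lapply(hours, function(h) {
    a <- A[, h + 1L]; a <- a[!is.na(a)]
    b <- B[, h + 1L]; b <- b[!is.na(b)]
    if (length(a) < 2L || length(b) < 2L)
      return(data.frame(hour = h, n_a = length(a), n_b = length(b),
                        median_a = NA_real_, median_b = NA_real_,
                        p = NA_real_, skipped = TRUE))
    data.frame(hour = h, n_a = length(a), n_b = length(b),
               median_a = median(a), median_b = median(b),
               p = mw_test_p(a, b), skipped = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- NA_real_
  out$significant <- FALSE
  tested <- !out$skipped
  if (any(tested)) {
    adj <- bky_fdr(out$p[tested], q)
    out$p_adj[tested] <- adj$adjusted_p
    out$significant[tested] <- adj$reject
  }
  out
}

#' Friedman comparison of daytime hourly %TF against the night reference
#'
#' Subjects are blocks; the treatments are the 16 daytime clock hours
#' (07:00-22:59) plus each subject's night-reference %TF as a 17th column.
#' The omnibus Friedman test asks whether %TF differs across these columns;
#' post-hoc, each daytime hour is compared against the night reference with
#' a paired two-tailed Wilcoxon signed-rank test, BKY-adjusted.
#'
#' Subjects missing any daytime bin or the night reference are excluded
#' (consistent with restricting to complete observation rather than
#' imputing).
#'
#' @param profiles list of `fog_hourly_profile`.
#' @param daytime daytime clock hours (default 7:22).
#' @param night_hours night window for the reference.
#' @param q FDR level for the post-hoc adjustment.
#' @return list: `statistic`, `df`, `p_value`, `posthoc` data.frame,
#'   `n_subjects`, `n_excluded`.
#' @export
daytime_vs_night <- function(profiles, daytime = 7:22,
                             night_hours = c(23, 0:6), q = 0.05) {
  rows <- lapply(profiles, function(p) {
    week <- if (inherits(p, "fog_hourly_profile")) p$week_avg else as.numeric(p)
    day_vals <- week[daytime + 1L]
    ref <- suppressWarnings(night_reference(week, night_hours))
    if (anyNA(day_vals) || is.na(ref)) return(NULL)
    c(day_vals, ref)
  })
  keep <- !vapply(rows, is.null, logical(1))
  X <- do.call(rbind, rows[keep])
  if (is.null(X) || nrow(X) < 3L)
    stop_insufficient("need at least 3 complete subjects for the Friedman comparison")
  colnames(X) <- c(sprintf("h%02d", daytime), "night_ref")
  fr <- friedman_safe(X)
  ph_p <- vapply(seq_along(daytime), function(j) {
    d <- X[, j] - X[, ncol(X)]
    if (all(d == 0)) return(1)
    suppressWarnings(wilcox.test(X[, j], X[, ncol(X)], paired = TRUE,
                                 alternative = "two.sided")$p.value)
  }, numeric(1))
  adj <- bky_fdr(ph_p, q)
  list(statistic = unname(fr$statistic), df = unname(fr$parameter),
       p_value = fr$p.value,
       posthoc = data.frame(hour = daytime, p = ph_p,
                            p_adj = adj$adjusted_p, significant = adj$reject),
       n_subjects = nrow(X), n_excluded = sum(!keep))
}

#' Split freezers into moderate and severe groups by NFOG-Q score
#'
#' Moderate: score <= cutoff; severe: score > cutoff. The default cutoff is
#' the cohort median score (20 in the original cohort). Freezers with a
#' missing score are excluded with a warning.
#'
#' @param manifest data.frame with `subject_id`, `group` (`"freezer"` /
#'   `"non_freezer"`) and `nfogq`.
#' @param cutoff NFOG-Q cutoff; default the freezer median.
#' @return the manifest with a `severity_group` column
#'   (`non_freezer` / `moderate` / `severe`); attribute `cutoff`.
#' @export
severity_split <- function(manifest, cutoff = NULL) {
  fr <- manifest$group == "freezer"
  miss <- fr & is.na(manifest$nfogq)
  if (any(miss)) {
    warning(sprintf("%d freezer(s) without NFOG-Q score excluded", sum(miss)))
    manifest <- manifest[!miss, , drop = FALSE]
    fr <- manifest$group == "freezer"
  }
  if (is.null(cutoff)) cutoff <- median(manifest$nfogq[fr])
  manifest$severity_group <- ifelse(!fr, "non_freezer",
                                    ifelse(manifest$nfogq <= cutoff,
                                           "moderate", "severe"))
  attr(manifest, "cutoff") <- cutoff
  manifest
}

#' Omnibus and post-hoc comparison of severity groups' daytime %TF
#'
#' Group mean week-averaged %TF is computed per daytime hour, giving a
#' blocked table (hours as blocks, groups as treatments); a Friedman test
#' provides the omnibus comparison and Dunn's mean-rank test the pairwise
#' post-hocs (BKY-adjusted).
#'
#' @param profile_groups named list of profile lists (or week matrices), one
#'   per group.
#' @param daytime daytime clock hours.
#' @param q FDR level.
#' @return list: `friedman` (statistic, df, p_value), `dunn` data.frame,
#'   `table` the hours x groups block table.
#' @export
severity_comparison <- function(profile_groups, daytime = 7:22, q = 0.05) {
  if (length(profile_groups) < 3L)
    stop_insufficient("need at least three groups")
  cols <- lapply(profile_groups, function(g) {
    M <- profiles_to_matrix(g)
    colMeans(M[, daytime + 1L, drop = FALSE], na.rm = TRUE)
  })
  tab <- do.call(cbind, cols)
  rownames(tab) <- sprintf("h%02d", daytime)
  keep <- stats::complete.cases(tab)
  tab <- tab[keep, , drop = FALSE]
  if (nrow(tab) < 3L)
    stop_insufficient("fewer than 3 complete hour blocks")
  fr <- friedman_safe(tab)
  list(friedman = list(statistic = unname(fr$statistic),
                       df = unname(fr$parameter), p_value = fr$p.value),
       dunn = dunn_posthoc(tab, q), table = tab)
}

#' Paired comparison of FOG-class time shares between settings
#'
#' Per class, a two-tailed Wilcoxon signed-rank test on paired per-subject
#' class shares (e.g. FOG-provoking protocol vs daily living). P-values are
#' reported unadjusted. When all paired differences are zero the p-value is
#' 1 by convention, flagged in `all_zero`.
#'
#' @param shares_a,shares_b subjects x 3 matrices of per-class %TF shares,
#'   same subject order.
#' @return data.frame (`fog_class`, `p`, `all_zero`).
#' @export
class_distribution_comparison <- function(shares_a, shares_b) {
  shares_a <- as.matrix(shares_a); shares_b <- as.matrix(shares_b)
  if (!all(dim(shares_a) == dim(shares_b)))
    stop_alignment("paired share matrices differ in shape")
  res <- lapply(1:3, function(j) {
    d <- shares_a[, j] - shares_b[, j]
    if (all(d == 0))
      return(data.frame(fog_class = FOG_CLASSES[j], p = 1, all_zero = TRUE))
    p <- suppressWarnings(wilcox.test(shares_a[, j], shares_b[, j],
                                      paired = TRUE,
                                      alternative = "two.sided")$p.value)
    data.frame(fog_class = FOG_CLASSES[j], p = p, all_zero = FALSE)
  })
  do.call(rbind, res)
}

#' Locate the peaks of a 24-hour %TF profile
#'
#' Convenience for recovery analyses: returns the clock hours of the largest
#' local maxima of a week-averaged hourly curve, at least `min_sep` hours
#' apart.
#'
#' @param week_avg 24-vector (NA bins allowed).
#' @param n_peaks number of peaks to return.
#' @param min_sep minimum separation in hours.
#' @return integer clock hours, ordered by peak height.
#' @export
profile_peaks <- function(week_avg, n_peaks = 2, min_sep = 4) {
  v <- week_avg
  v[is.na(v)] <- -Inf
  ord <- order(v, decreasing = TRUE)
  peaks <- integer()
  for (h in ord - 1L) {
    if (!length(peaks) || all(pmin(abs(h - peaks), 24 - abs(h - peaks)) >= min_sep))
      peaks <- c(peaks, h)
    if (length(peaks) == n_peaks) break
  }
  peaks
}
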