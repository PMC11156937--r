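# Rater-agreement statistics: two-way absolute-agreement intraclass
# correlations (single-measure and mean-of-k) with F-based confidence
# intervals, and Cohen's d.

# two-way crossed ANOVA mean squares of an n x k complete ratings matrix
icc_mean_squares <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop_validation("missing cells are not supported; drop incomplete rows")
  n <- nrow(x); k <- ncol(x)
  if (n < 3L) stop_validation("need at least 3 subjects (rows)")
  if (k < 2L) stop_validation("need at least 2 raters (columns)")
  g <- mean(x)
  rm_ <- rowMeans(x); cm <- colMeans(x)
  ssr <- k * sum((rm_ - g)^2)
  ssc <- n * sum((cm - g)^2)
  sst <- sum((x - g)^2)
  sse <- sst - ssr - ssc
  list(n = n, k = k, msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)), sst = sst)
}

icc_ci_single <- function(ms, icc, conf) {
  n <- ms$n; k <- ms$k
  alpha <- 1 - conf
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  vn <- (a * ms$msc + b * ms$mse)^2
  vd <- (a * ms$msc)^2 / (k - 1) + (b * ms$mse)^2 / ((n - 1) * (k - 1))
  v <- vn / vd
  # McGraw-Wong F-method bounds for absolute-agreement single-measure ICC
  lower <- n * (ms$msr - qf(1 - alpha / 2, n - 1, v) * ms$mse) /
    (qf(1 - alpha / 2, n - 1, v) * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
  upper <- n * (qf(1 - alpha / 2, v, n - 1) * ms$msr - ms$mse) /
    (k * ms$msc + (k * n - k - n) * ms$mse + n * qf(1 - alpha / 2, v, n - 1) * ms$msr)
  c(max(-1, lower), min(1, upper))
}

icc_result <- function(ms, estimate, ci, form) {
  f <- ms$msr / ms$mse
  df1 <- ms$n - 1; df2 <- (ms$n - 1) * (ms$k - 1)
  structure(list(estimate = estimate, ci95 = ci, f_value = f,
                 df1 = df1, df2 = df2,
                 p_value = pf(f, df1, df2, lower.tail = FALSE),
                 form = form, n = ms$n, k = ms$k),
            class = "fog_icc")
}

#' @export
print.fog_icc <- function(x, ...) {
  cat(sprintf("ICC %s = %.3f (95%% CI %.3f-%.3f), F(%d,%d) = %.2f, p = %.3g\n",
              x$form, x$estimate, x$ci95[1], x$ci95[2], x$df1, x$df2,
              x$f_value, x$p_value))
  invisible(x)
}

#' Single-measure two-way absolute-agreement ICC
#'
#' Shrout-Fleiss ICC(2,1) / McGraw-Wong ICC(A,1): a two-way random-effects
#' decomposition of an n-subjects-by-k-raters matrix into row, column and
#' error mean squares,
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#' Absolute agreement penalizes systematic rater bias, which is what makes
#' it the right form for comparing model-estimated outcomes against
#' gold-standard values. Confidence intervals use the F-distribution method;
#' the reported p-value tests ICC = 0 via F = MSR/MSE.
#'
#' @param x numeric n x k matrix, complete (no missing cells — incomplete
#'   subjects should be dropped, not imputed).
#' @param conf confidence level (default 0.95).
#' @return object of class `fog_icc`.
#' @export
icc_2_1 <- function(x, conf = 0.95) {
  ms <- icc_mean_squares(x)
  if (ms$sst <= 1e-12 * ms$n * ms$k)
    stop_undefined_metric("ICC undefined: zero total variance")
  est <- (ms$msr - ms$mse) /
    (ms$msr + (ms$k - 1) * ms$mse + ms$k * (ms$msc - ms$mse) / ms$n)
  icc_result(ms, est, icc_ci_single(ms, est, conf), "icc_2_1_absolute_single")
}

#' Mean-rating absolute-agreement ICC
#'
#' McGraw-Wong ICC(A,k): agreement of the k-rater mean,
#' `(MSR - MSE) / (MSR + (MSC - MSE) / n)`. Used here for day-to-day
#' stability of daily percent time frozen with k = 6 days. Confidence bounds
#' are the single-measure absolute-agreement bounds passed through the
#' mean-of-k transform `k L / (1 + (k-1) L)`.
#'
#' @inheritParams icc_2_1
#' @return object of class `fog_icc`.
#' @export
icc_a_k <- function(x, conf = 0.95) {
  ms <- icc_mean_squares(x)
  if (ms$sst <= 1e-12 * ms$n * ms$k)
    stop_undefined_metric("ICC undefined: zero total variance")
  est <- (ms$msr - ms$mse) / (ms$msr + (ms$msc - ms$mse) / ms$n)
  single <- (ms$msr - ms$mse) /
    (ms$msr + (ms$k - 1) * ms$mse + ms$k * (ms$msc - ms$mse) / ms$n)
  ci1 <- icc_ci_single(ms, single, conf)
  cik <- ms$k * ci1 / (1 + (ms$k - 1) * ci1)
  icc_result(ms, est, cik, "icc_a_k_absolute_mean")
}

#' Cohen's d with pooled standard deviation
#'
#' `(mean_a - mean_b) / s_p`, with `s_p` the df-weighted pooled SD.
#'
#' @param group_a,group_b numeric vectors (each of length >= 2).
#' @return standardized mean difference.
#' @export
cohens_d <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) stop_validation("each group needs n >= 2")
  sp2 <- ((na - 1) * var(group_a) + (nb - 1) * var(group_b)) / (na + nb - 2)
  if (sp2 <= 0) stop_undefined_metric("Cohen's d undefined: zero pooled SD")
  (mean(group_a) - mean(group_b)) / sqrt(sp2)
}
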