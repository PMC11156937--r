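# Benjamini-Krieger-Yekutieli two-stage linear step-up FDR control, and the
# Dunn mean-rank post-hoc z test used after a Friedman omnibus.

# linear (BH) step-up at level alpha: reject the r largest-p hypotheses with
# p_(i) <= i * alpha / m for the largest such i
bh_step_up <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ok <- p[o] <= seq_len(m) * alpha / m
  r <- if (any(ok)) max(which(ok)) else 0L
  reject <- rep(FALSE, m)
  if (r > 0L) reject[o[seq_len(r)]] <- TRUE
  reject
}

bky_reject <- function(p, q) {
  m <- length(p)
  q1 <- q / (1 + q)
  stage1 <- bh_step_up(p, q1)
  r1 <- sum(stage1)
  if (r1 == 0L) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  bh_step_up(p, q1 * m / (m - r1))
}

#' Two-stage Benjamini-Krieger-Yekutieli FDR procedure
#'
#' Stage 1 runs the linear step-up procedure at level `q' = q / (1 + q)` to
#' estimate the number of true nulls; with `r1` stage-1 rejections, stage 2
#' re-runs the step-up at `q' * m / (m - r1)` (rejecting nothing if
#' `r1 = 0`, everything if `r1 = m`). The adjusted p-value of a hypothesis
#' is the smallest nominal `q` at which it would be rejected (1 if none),
#' found by bisection — rejection regions grow monotonically with `q`.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param q target false-discovery rate (default 0.05).
#' @return list(`reject` logical, `adjusted_p` numeric, `q`).
#' @export
bky_fdr <- function(p_values, q = 0.05) {
  p <- as.numeric(p_values)
  if (length(p) == 0L) return(list(reject = logical(), adjusted_p = numeric(), q = q))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop_validation("p-values must lie in [0, 1]")
  reject <- bky_reject(p, q)
  adjusted <- vapply(seq_along(p), function(i) {
    if (!bky_reject(p, 1)[i]) return(1)
    lo <- 0; hi <- 1
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      if (bky_reject(p, mid)[i]) hi <- mid else lo <- mid
    }
    hi
  }, numeric(1))
  list(reject = reject, adjusted_p = adjusted, q = q)
}

#' Dunn mean-rank post-hoc comparisons after a Friedman test
#'
#' For a blocked design with `n` blocks and `k` treatments ranked within
#' blocks, the pairwise z statistic is the difference of mean ranks divided
#' by `sqrt(k (k + 1) / (6 n))`; two-sided normal p-values are adjusted with
#' [bky_fdr].
#'
#' @param y n x k matrix, blocks in rows, treatments in columns.
#' @param q FDR level for the adjustment.
#' @return data.frame of pairwise comparisons (`z`, `p`, `p_adj`,
#'   `significant`).
#' @export
dunn_posthoc <- function(y, q = 0.05) {
  y <- as.matrix(y)
  n <- nrow(y); k <- ncol(y)
  if (is.null(colnames(y))) colnames(y) <- paste0("g", seq_len(k))
  ranks <- t(apply(y, 1, rank))
  mean_rank <- colMeans(ranks)
  se <- sqrt(k * (k + 1) / (6 * n))
  pairs <- utils::combn(k, 2)
  z <- (mean_rank[pairs[1, ]] - mean_rank[pairs[2, ]]) / se
  p <- 2 * pnorm(-abs(z))
  adj <- bky_fdr(p, q)
  data.frame(group_a = colnames(y)[pairs[1, ]],
             group_b = colnames(y)[pairs[2, ]],
             mean_rank_a = mean_rank[pairs[1, ]],
             mean_rank_b = mean_rank[pairs[2, ]],
             z = z, p = p, p_adj = adj$adjusted_p,
             significant = adj$reject, row.names = NULL)
}
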