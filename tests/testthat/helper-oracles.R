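# Independent oracles and fixture builders shared across the suite.

# --- brute-force threshold-enumeration oracles for ranking metrics --------

oracle_ap <- function(labels, scores) {
  labels <- as.logical(labels)
  npos <- sum(labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  prev_r <- 0; ap <- 0
  for (t in thr) {
    dec <- scores >= t
    p <- sum(labels & dec) / sum(dec)
    r <- sum(labels & dec) / npos
    ap <- ap + (r - prev_r) * p
    prev_r <- r
  }
  ap
}

oracle_pr <- function(labels, scores) {
  labels <- as.logical(labels)
  npos <- sum(labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  do.call(rbind, lapply(thr, function(t) {
    dec <- scores >= t
    data.frame(threshold = t, precision = sum(labels & dec) / sum(dec),
               recall = sum(labels & dec) / npos)
  }))
}

oracle_roc <- function(labels, scores) {
  labels <- as.logical(labels)
  npos <- sum(labels); nneg <- sum(!labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- rbind(data.frame(fpr = 0, tpr = 0),
               do.call(rbind, lapply(thr, function(t) {
                 dec <- scores >= t
                 data.frame(fpr = sum(!labels & dec) / nneg,
                            tpr = sum(labels & dec) / npos)
               })))
  auc <- 0
  for (i in 2:nrow(pts))
    auc <- auc + (pts$fpr[i] - pts$fpr[i - 1]) * (pts$tpr[i] + pts$tpr[i - 1]) / 2
  list(points = pts, auc = auc)
}

# random scored instance with deliberate tie mass
random_instance <- function(max_len = 12) {
  n <- sample(2:max_len, 1)
  labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
  if (!any(labels)) labels[sample(n, 1)] <- TRUE
  scores <- if (runif(1) < 0.5)
    sample(seq(0, 1, by = 0.25), n, replace = TRUE)  # heavy ties
  else round(runif(n), sample(1:3, 1))
  list(labels = labels, scores = scores)
}

# --- ANOVA sums-of-squares oracle for the ICC forms -----------------------

oracle_icc_ms <- function(x) {
  n <- nrow(x); k <- ncol(x)
  d <- data.frame(y = as.vector(x),
                  subj = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(y ~ subj + rater, data = d))[[1]]
  list(n = n, k = k,
       msr = tab["subj", "Mean Sq"],
       msc = tab["rater", "Mean Sq"],
       mse = tab["Residuals", "Mean Sq"])
}

oracle_icc_2_1 <- function(x) {
  ms <- oracle_icc_ms(x)
  (ms$msr - ms$mse) /
    (ms$msr + (ms$k - 1) * ms$mse + ms$k * (ms$msc - ms$mse) / ms$n)
}

oracle_icc_a_k <- function(x) {
  ms <- oracle_icc_ms(x)
  (ms$msr - ms$mse) / (ms$msr + (ms$msc - ms$mse) / ms$n)
}

# panels with known population ICC(2,1) = rho (subject, rater, error
# variance components)
simulate_icc_panel <- function(n, k, rho, var_col_frac = 0.05) {
  stopifnot(rho > 0, rho < 1)
  var_r <- rho
  var_rest <- 1 - rho
  var_c <- var_col_frac * var_rest
  var_e <- var_rest - var_c
  r <- rnorm(n, 0, sqrt(var_r))
  cc <- rnorm(k, 0, sqrt(var_c))
  outer(r, cc, `+`) + matrix(rnorm(n * k, 0, sqrt(var_e)), n, k)
}

# --- literal two-stage BKY definition -------------------------------------

oracle_bky <- function(p, q) {
  m <- length(p)
  step_up <- function(alpha) {
    o <- order(p); ps <- p[o]
    r <- 0
    for (i in m:1) if (ps[i] <= i * alpha / m) { r <- i; break }
    rej <- rep(FALSE, m)
    if (r > 0) rej[o[1:r]] <- TRUE
    rej
  }
  q1 <- q / (1 + q)
  s1 <- step_up(q1)
  r1 <- sum(s1)
  if (r1 == 0) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  step_up(q1 * m / (m - r1))
}

# --- exact two-sided Wilcoxon signed-rank enumeration (tie-free d) --------

oracle_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_null <- as.matrix(signs) %*% rk
  p_le <- mean(w_null <= w_obs)
  p_ge <- mean(w_null >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# --- small CSV fixture builders -------------------------------------------

write_tdcsfog_fixture <- function(path, n = 4, labels = NULL, extra_col = NULL) {
  df <- data.frame(Time = 0:(n - 1),
                   AccV = round(rnorm(n, 9.8, 0.5), 6),
                   AccML = round(rnorm(n, 0, 0.5), 6),
                   AccAP = round(rnorm(n, 0, 0.5), 6),
                   StartHesitation = 0L, Turn = 0L, Walking = 0L)
  if (!is.null(labels)) for (nm in names(labels)) df[[nm]] <- labels[[nm]]
  if (!is.null(extra_col)) df[[extra_col]] <- 0L
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

write_defog_fixture <- function(path, acc, valid, task,
                                turn = 0L) {
  n <- nrow(acc)
  df <- data.frame(Time = 0:(n - 1), AccV = acc[, 1], AccML = acc[, 2],
                   AccAP = acc[, 3], StartHesitation = 0L, Turn = turn,
                   Walking = 0L, Valid = valid, Task = task)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
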