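# Daily-living pipeline pieces: bout masks, ensembling, hourly/daily %TF,
# the night reference, BKY FDR and the group-comparison statistics.

test_that("bout padding follows the 5-second interval arithmetic", {
  bouts <- data.frame(start = 100, end = 200)
  m <- expand_bouts(bouts, pad_s = 5, n = 2000, sampling_rate = 100)
  expect_identical(which(m), 1:700)                 # [max(0, -400), 700)
  m0 <- expand_bouts(bouts, pad_s = 0, n = 2000, sampling_rate = 100)
  expect_identical(which(m0), 101:200)
  two <- data.frame(start = c(10, 30), end = c(20, 40))
  m2 <- expand_bouts(two, pad_s = 5, n = 60, sampling_rate = 1)
  expect_identical(which(m2), 6:45)                 # padded bouts merge
})

test_that("OR ensemble is pointwise and never lowers %TF", {
  expect_identical(ensemble_or(list(c(0, 1, 0), c(1, 1, 0))),
                   c(TRUE, TRUE, FALSE))
  expect_identical(ensemble_or(list(c(TRUE, FALSE))), c(TRUE, FALSE))
  expect_error(ensemble_or(list(c(1, 0), c(1, 0, 1))),
               class = "fog_alignment_error")
  set.seed(51)
  t0 <- as.POSIXct("2024-03-04 00:00:00", tz = "UTC")
  for (i in 1:50) {
    n <- 3600
    members <- replicate(3, runif(n) < 0.1, simplify = FALSE)
    mask <- runif(n) < 0.7
    tf <- function(dec) {
      s <- hourly_tf(dec, mask, t0, 1)
      s$week_avg[!is.na(s$week_avg)]
    }
    expect_true(all(tf(ensemble_or(members)) >=
                      do.call(pmax, lapply(members, tf)) - 1e-12))
  }
})

test_that("hourly %TF bins by clock hour with undefined empty bins", {
  t0 <- as.POSIXct("2024-03-04 00:00:00", tz = "UTC")
  n <- 3 * 3600
  mask <- c(rep(TRUE, 600), rep(FALSE, 3000),          # hour 0: 600 s bouts
            rep(FALSE, 3600),                          # hour 1: no bouts
            rep(TRUE, 1000), rep(FALSE, 2600))         # hour 2
  dec <- logical(n)
  dec[1:60] <- TRUE                                    # 60 s FOG in hour 0
  p <- hourly_tf(dec, mask, t0, 1)
  expect_equal(p$tf[1, 1], 10)
  expect_true(is.na(p$tf[1, 2]))
  expect_equal(p$tf[1, 3], 0)
  expect_equal(p$bout_seconds[1, 3], 1000)
})

test_that("daily %TF equals the bout-time-weighted mean of hourly %TF", {
  set.seed(52)
  t0 <- as.POSIXct("2024-03-04 06:30:00", tz = "UTC")  # offset start clock
  for (i in 1:20) {
    n <- 30 * 3600
    mask <- runif(n) < 0.2
    dec <- runif(n) < 0.05
    p <- hourly_tf(dec, mask, t0, 1)
    for (d in seq_len(nrow(p$tf))) {
      w <- p$bout_seconds[d, ]
      def <- !is.na(p$tf[d, ])
      if (!any(def)) next
      expect_equal(p$daily[d], sum(p$tf[d, def] * w[def]) / sum(w[def]),
                   tolerance = 1e-9)
    }
  }
})

test_that("daily %TF endpoints: no FOG is 0, all-frozen bouts are 100", {
  t0 <- as.POSIXct("2024-03-04 00:00:00", tz = "UTC")
  n <- 2 * 86400
  mask <- rep(c(TRUE, FALSE), n / 2)
  expect_equal(daily_tf(logical(n), mask, t0, 1), c(0, 0))
  expect_equal(daily_tf(mask, mask, t0, 1), c(100, 100))
})

test_that("night reference is the median of defined night bins", {
  week <- rep(NA_real_, 24)
  week[c(24, 1:7)] <- 0                        # hours 23, 0..6 all zero
  expect_equal(night_reference(week), 0)
  week2 <- rep(NA_real_, 24); week2[2] <- 7.5  # single defined night bin
  expect_equal(night_reference(week2), 7.5)
  week3 <- rep(10, 24); week3[c(1, 2, 3) ] <- c(1, 5, 9)
  expect_equal(night_reference(week3, night_hours = 0:2), 5)
  expect_warning(ref <- night_reference(rep(NA_real_, 24)))
  expect_true(is.na(ref))
})

test_that("BKY two-stage procedure matches its literal definition", {
  r <- bky_fdr(0.01, q = 0.05)
  expect_true(r$reject)                        # 0.01 <= 0.05 / 1.05
  expect_false(any(bky_fdr(rep(0.9, 10))$reject))
  set.seed(53)
  for (i in 1:200) {
    m <- sample(1:12, 1)
    p <- switch(sample(3, 1), runif(m), round(runif(m), 2),
                rbeta(m, 0.3, 3))
    q <- sample(c(0.01, 0.05, 0.1, 0.25), 1)
    expect_identical(bky_fdr(p, q)$reject, oracle_bky(p, q))
  }
  expect_error(bky_fdr(c(0.5, 1.2)), class = "fog_validation_error")
})

test_that("BKY adjusted p-values are consistent with rejection at q", {
  set.seed(54)
  for (i in 1:40) {
    m <- sample(2:10, 1)
    p <- runif(m)
    q <- runif(1, 0.01, 0.4)
    r <- bky_fdr(p, q)
    expect_identical(r$reject, r$adjusted_p <= q + 1e-9)
  }
})

test_that("group comparison: identical groups null, disjoint groups exact", {
  same <- matrix(rep(c(1, 2, 3, 4), 24), 4, 24)
  r <- compare_groups_hourly(same, same)
  expect_true(all(r$p == 1))
  expect_false(any(r$significant))
  a <- matrix(rep(1:4, 24), 4, 24)
  b <- matrix(rep(5:8, 24), 4, 24)
  r2 <- compare_groups_hourly(a, b)
  expect_equal(r2$p, rep(2 / 70, 24), tolerance = 1e-12)
  # skipped hours: group too small after NA removal
  a_na <- a; a_na[2:4, 1] <- NA
  r3 <- compare_groups_hourly(a_na, b)
  expect_true(r3$skipped[1])
  expect_false(any(r3$skipped[-1]))
})

test_that("daytime-vs-night: flat profiles are null, shifts are detected", {
  flat <- lapply(1:6, function(i) rep(i, 24))
  r <- daytime_vs_night(flat)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_true(all(r$posthoc$p == 1))
  # a single uniformly shifted daytime hour is flagged in most runs
  set.seed(55)
  hits <- replicate(10, {
    profs <- lapply(1:30, function(i) {
      w <- rep(abs(rnorm(1, 2, 0.5)), 24) + rnorm(24, 0, 0.3)
      w[13] <- w[13] + 3        # hour 12
      pmax(w, 0)
    })
    rr <- daytime_vs_night(profs)
    rr$posthoc$p_adj[rr$posthoc$hour == 12] < 0.05
  })
  expect_gte(mean(hits), 0.9)
  expect_error(daytime_vs_night(flat[1:2]),
               class = "fog_insufficient_data_error")
})

test_that("severity split honors the cutoff and boundary rule", {
  man <- data.frame(subject_id = c("a", "b"), group = "freezer",
                    nfogq = c(18, 24))
  s <- severity_split(man, cutoff = 20)
  expect_identical(s$severity_group, c("moderate", "severe"))
  all20 <- data.frame(subject_id = letters[1:4], group = "freezer", nfogq = 20)
  expect_true(all(severity_split(all20)$severity_group == "moderate"))
  man_na <- rbind(man, data.frame(subject_id = "c", group = "freezer",
                                  nfogq = NA))
  expect_warning(s2 <- severity_split(man_na, cutoff = 20))
  expect_equal(nrow(s2), 2L)
})

test_that("generated cohort splits 25 moderate / 20 severe at the median", {
  man <- generate_cohort(seed = 9)
  s <- severity_split(man)
  expect_equal(attr(s, "cutoff"), 20)
  expect_equal(sum(s$severity_group == "moderate"), 25)
  expect_equal(sum(s$severity_group == "severe"), 20)
  expect_equal(sum(s$severity_group == "non_freezer"), 19)
  # severity increases with the questionnaire score by construction
  fr <- s[s$group == "freezer", ]
  expect_gt(min(fr$severity[fr$severity_group == "severe"]),
            max(fr$severity[fr$severity_group == "moderate"]) - 1e-12)
})

test_that("Dunn post-hoc z matches the mean-rank arithmetic", {
  # 4 blocks, 3 groups in strict order: mean ranks 1, 2, 3
  tab <- cbind(g1 = c(1, 2, 3, 4), g2 = c(2, 3, 4, 5), g3 = c(3, 4, 5, 6))
  d <- dunn_posthoc(tab)
  se <- sqrt(3 * 4 / (6 * 4))
  expect_equal(d$z[d$group_a == "g1" & d$group_b == "g3"], -2 / se,
               tolerance = 1e-12)
  expect_equal(d$z[d$group_a == "g1" & d$group_b == "g2"], -1 / se,
               tolerance = 1e-12)
  set.seed(57)
  same_week <- matrix(rep(runif(24, 0, 3), each = 3), nrow = 3)
  ident <- severity_comparison(list(a = same_week, b = same_week,
                                    c = same_week))
  expect_equal(ident$friedman$statistic, 0)
  expect_false(any(ident$dunn$significant))
})

test_that("paired class-share comparison: exact signed-rank behavior", {
  same <- matrix(c(10, 80, 10), 4, 3, byrow = TRUE)
  r <- class_distribution_comparison(same, same)
  expect_true(all(r$p == 1))
  expect_true(all(r$all_zero))
  # strictly ordered pairs, n = 8: two-sided exact p = 2/256
  a <- matrix(0, 8, 3); b <- matrix(0, 8, 3)
  a[, 2] <- 81:88; b[, 2] <- a[, 2] - (1:8)
  r2 <- class_distribution_comparison(a, b)
  expect_equal(r2$p[2], 2 / 256, tolerance = 1e-12)
  set.seed(56)
  for (i in 1:20) {
    n <- sample(5:10, 1)
    x <- matrix(rnorm(n * 3), n, 3); y <- matrix(rnorm(n * 3), n, 3)
    r3 <- class_distribution_comparison(x, y)
    for (j in 1:3)
      expect_equal(r3$p[j], oracle_signrank_p(x[, j] - y[, j]),
                   tolerance = 1e-12)
  }
})

test_that("profile peak finder returns separated local maxima", {
  v <- rep(1, 24); v[8] <- 5; v[23] <- 4; v[9] <- 4.5
  expect_identical(sort(profile_peaks(v)), c(7L, 22L))
})
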