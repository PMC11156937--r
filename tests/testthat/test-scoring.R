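# Competition scoring: average precision, curves, pooled mAP.

test_that("average precision reproduces the hand-computed step sum", {
  # thresholds 0.9, 0.8, 0.7, 0.6: AP = 0.5*1 + 0.5*(2/3) = 5/6
  expect_equal(average_precision(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.6)),
               5 / 6, tolerance = 1e-15)
  # perfect separation
  expect_equal(average_precision(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  # masked-out positives are an undefined metric, never a silent zero
  expect_error(average_precision(c(1, 0), c(0.9, 0.1), mask = c(0, 1)),
               class = "fog_undefined_metric")
})

test_that("AP, PR and ROC match brute-force threshold enumeration", {
  set.seed(11)
  for (i in 1:300) {
    inst <- random_instance()
    expect_equal(average_precision(inst$labels, inst$scores),
                 oracle_ap(inst$labels, inst$scores), tolerance = 1e-12)
    pc <- pr_curve(inst$labels, inst$scores)
    oc <- oracle_pr(inst$labels, inst$scores)
    expect_equal(pc$precision[-1], oc$precision, tolerance = 1e-12)
    expect_equal(pc$recall[-1], oc$recall, tolerance = 1e-12)
    if (any(inst$labels) && !all(inst$labels)) {
      rc <- roc_curve(inst$labels, inst$scores)
      or <- oracle_roc(inst$labels, inst$scores)
      expect_equal(auc(rc), or$auc, tolerance = 1e-12)
      expect_equal(rc$fpr[-1], or$points$fpr[-1], tolerance = 1e-12)
      expect_equal(rc$tpr[-1], or$points$tpr[-1], tolerance = 1e-12)
    }
  }
})

test_that("metrics are invariant under strictly monotone score transforms", {
  set.seed(12)
  for (i in 1:50) {
    inst <- random_instance()
    for (f in list(function(x) exp(3 * x), function(x) x^3 + 2 * x)) {
      expect_equal(average_precision(inst$labels, f(inst$scores)),
                   average_precision(inst$labels, inst$scores),
                   tolerance = 1e-12)
      if (any(inst$labels) && !all(inst$labels))
        expect_equal(auc(roc_curve(inst$labels, f(inst$scores))),
                     auc(roc_curve(inst$labels, inst$scores)),
                     tolerance = 1e-12)
    }
  }
})

test_that("masked metric equals the metric of the mask-compressed series", {
  set.seed(13)
  for (i in 1:50) {
    inst <- random_instance()
    mask <- sample(c(TRUE, FALSE), length(inst$labels), replace = TRUE,
                   prob = c(0.8, 0.2))
    if (!any(inst$labels & mask)) next
    expect_equal(average_precision(inst$labels, inst$scores, mask),
                 average_precision(inst$labels[mask], inst$scores[mask]),
                 tolerance = 1e-15)
  }
})

test_that("anti-ranked scores give AUC 0 and perfect ranking gives 1", {
  expect_equal(auc(roc_curve(c(1, 1, 0), c(0.9, 0.8, 0.1))), 1)
  expect_equal(auc(roc_curve(c(1, 1, 0), c(0.1, 0.2, 0.9))), 0)
  expect_error(roc_curve(c(1, 1), c(0.5, 0.4)), class = "fog_undefined_metric")
})

make_session_labels <- function(sh, tu, wa, notype = FALSE, valid = TRUE,
                                task = TRUE) {
  fog_labels(length(sh), start_hesitation = sh, turn = tu, walking = wa,
             notype = notype, valid = valid, task = task)
}

test_that("mAP is the unweighted mean of per-class pooled APs", {
  # perfectly ranked in all three classes
  lb <- make_session_labels(c(1, 0, 0, 0, 0, 0), c(0, 0, 1, 0, 0, 0),
                            c(0, 0, 0, 0, 1, 0))
  sc <- fog_scores(cbind(c(9, 1, 1, 1, 1, 1), c(1, 1, 9, 1, 1, 1),
                         c(1, 1, 1, 1, 9, 1)))
  r <- mean_average_precision(list(lb), list(sc))
  expect_equal(unname(r$per_class), c(1, 1, 1))
  expect_equal(r$mAP, 1)

  # definition: mean of class APs computed on disjoint toy sets
  set.seed(14)
  lb2 <- make_session_labels(c(1, 0, 1, 0, 0, 0), c(0, 0, 0, 0, 1, 1),
                             rep(0, 6))
  lb2$walking[2] <- FALSE
  sc2 <- fog_scores(matrix(runif(18), 6, 3))
  lb3 <- make_session_labels(rep(0, 4), rep(0, 4), c(1, 0, 0, 1))
  sc3 <- fog_scores(matrix(runif(12), 4, 3))
  r2 <- mean_average_precision(list(lb2, lb3), list(sc2, sc3))
  expect_equal(r2$mAP, mean(r2$per_class))
  expect_equal(length(r2$per_class), 3L)
})

test_that("notype samples are excluded from per-class scoring", {
  lb <- make_session_labels(rep(0, 5), c(1, 0, 0, 0, 0), rep(0, 5),
                            notype = c(0, 0, 1, 1, 0))
  # notype samples get the worst possible turn scores; excluding them means
  # the turn AP is still perfect
  sc <- fog_scores(cbind(rep(0, 5), c(0.9, 0.5, 0.1, 0.1, 0.4), rep(0, 5)))
  expect_error(mean_average_precision(list(lb), list(sc)),
               "start_hesitation", class = "fog_undefined_metric")
  ap_turn <- average_precision(lb$turn, sc[, "turn"],
                               mask = make_mask(lb) & !lb$notype)
  expect_equal(ap_turn, 1)
})

test_that("random-score detector attains AP near class prevalence", {
  set.seed(15)
  n <- 400
  prev <- 0.15
  aps <- replicate(50, {
    y <- runif(n) < prev
    if (!any(y)) y[1] <- TRUE
    average_precision(y, runif(n))
  })
  expect_lt(abs(mean(aps) - prev), 0.02)
})
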