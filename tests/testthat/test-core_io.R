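# Readers/writers for the session CSV dialects and the submission format.

test_that("tdcsfog fixture reads with schema identity and all-true flags", {
  f <- withr::local_tempfile(fileext = ".csv")
  set.seed(1)
  write_tdcsfog_fixture(f, n = 4)
  out <- read_recording(f, "tdcsfog")
  expect_equal(out$recording$n, 4L)
  expect_equal(out$recording$sampling_rate, 128)
  expect_false(any(any_fog(out$labels)))
  expect_true(all(out$labels$valid))
  expect_true(all(out$labels$task))
  expect_identical(make_mask(out$labels), rep(TRUE, 4))
})

test_that("defog Valid/Task flags conjoin into the evaluation mask", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_defog_fixture(f, acc = matrix(0.1, 3, 3), valid = c(1, 1, 0),
                      task = c(1, 0, 1))
  out <- read_recording(f, "defog")
  expect_identical(make_mask(out$labels), c(TRUE, FALSE, FALSE))
})

test_that("schema violations raise errors naming the offending column", {
  f <- withr::local_tempfile(fileext = ".csv")
  set.seed(2)
  write_tdcsfog_fixture(f, extra_col = "Valid")
  expect_error(read_recording(f, "tdcsfog"), "Valid",
               class = "fog_schema_error")
  write_tdcsfog_fixture(f)
  df <- utils::read.csv(f)
  utils::write.csv(df[, setdiff(names(df), "Turn")], f, row.names = FALSE)
  expect_error(read_recording(f, "tdcsfog"), "Turn",
               class = "fog_schema_error")
})

test_that("malformed files raise format errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  file.create(f)
  expect_error(read_recording(f, "tdcsfog"), class = "fog_format_error")
  set.seed(3)
  write_tdcsfog_fixture(f, n = 5)
  df <- utils::read.csv(f)
  df$Time <- c(0, 1, 2, 4, 5)            # skipped tick
  utils::write.csv(df, f, row.names = FALSE)
  expect_error(read_recording(f, "tdcsfog"), "non-uniform",
               class = "fog_format_error")
  expect_error(read_recording(file.path(tempdir(), "nope.csv"), "tdcsfog"),
               class = "fog_format_error")
})

test_that("g-unit dialects convert with the configured constant", {
  f <- withr::local_tempfile(fileext = ".csv")
  acc_g <- matrix(c(1.0, -0.5, 0.25, 0.125, 2, -1, 0.0625, 4, -2), 3, 3)
  write_defog_fixture(f, acc = acc_g, valid = 1L, task = 1L)
  out <- read_recording(f, "defog")
  expect_equal(out$recording$acc, acc_g * STANDARD_GRAVITY,
               ignore_attr = TRUE, tolerance = 1e-15)
  out2 <- read_recording(f, "defog", g_constant = 2)
  expect_equal(out2$recording$acc, acc_g * 2, ignore_attr = TRUE,
               tolerance = 1e-15)
  expect_identical(out$recording$units_in, "g")
})

test_that("recording write-then-read round-trips values", {
  d <- withr::local_tempdir()
  set.seed(4)
  for (dialect in c("tdcsfog", "defog")) {
    rec <- fog_recording(matrix(rnorm(30), 10, 3), c(tdcsfog = 128, defog = 100)[[dialect]],
                         dialect = dialect,
                         units_in = if (dialect == "defog") "g" else "m_per_s2")
    lab <- fog_labels(10, turn = c(rep(FALSE, 5), rep(TRUE, 3), FALSE, FALSE),
                      valid = rep(c(TRUE, TRUE, TRUE, TRUE, FALSE), 2))
    f <- file.path(d, paste0(dialect, ".csv"))
    write_recording(rec, lab, f)
    back <- read_recording(f, dialect)
    expect_equal(back$recording$acc, rec$acc, tolerance = 1e-13)
    expect_identical(back$labels$turn, lab$turn)
    if (dialect == "defog") expect_identical(back$labels$valid, lab$valid)
  }
})

test_that("submission IO round-trips at full float precision", {
  f <- withr::local_tempfile(fileext = ".csv")
  set.seed(5)
  scores <- list(sessA = fog_scores(matrix(runif(9), 3, 3)),
                 sessB = fog_scores(matrix(rnorm(6), 2, 3)))
  write_submission(scores, f)
  back <- read_submission(f)
  expect_identical(names(back), c("sessA", "sessB"))
  expect_identical(back$sessA, scores$sessA)
  expect_identical(back$sessB, scores$sessB)
})

test_that("submission edge cases: empty set, bad columns, duplicates, NaN", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_submission(list(), f)
  expect_identical(read_submission(f), list())
  writeLines(c("Id,StartHesitation,Turn", "a_0,0.1,0.2"), f)
  expect_error(read_submission(f), "Walking", class = "fog_format_error")
  writeLines(c("Id,StartHesitation,Turn,Walking", "a_0,0.1,0.2,0.3",
               "a_0,0.1,0.2,0.3"), f)
  expect_error(read_submission(f), class = "fog_format_error")
  expect_error(write_submission(list(a = matrix(NaN, 1, 3)), f),
               class = "fog_validation_error")
})

test_that("mask with padded bouts restricts and never adds samples", {
  lab <- fog_labels(8)
  bouts <- data.frame(start = 2, end = 6)   # samples 2..5
  m <- make_mask(lab, bouts, sampling_rate = 1, pad_s = 0)
  expect_identical(which(m), 3:6)           # 0-based samples 2..5
  # monotone: restricting an already-restricted mask never sets TRUE
  lab2 <- fog_labels(8, valid = c(rep(TRUE, 4), rep(FALSE, 4)))
  m2 <- make_mask(lab2, bouts, sampling_rate = 1, pad_s = 0)
  expect_true(all(m2 <= make_mask(lab2)))
  expect_true(all(m2 <= m))
  # idempotent on all-true flags without bouts
  expect_identical(make_mask(lab), rep(TRUE, 8))
})

test_that("label channels enforce mutual exclusivity", {
  expect_error(fog_labels(2, turn = c(TRUE, FALSE), walking = c(TRUE, FALSE)),
               class = "fog_validation_error")
  expect_error(fog_labels(2, turn = TRUE, notype = TRUE),
               class = "fog_validation_error")
})
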