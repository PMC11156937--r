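# Generator contracts: determinism, label structure, convergence to the
# configured episode statistics, spectral content, detector behavior.

test_that("generators are deterministic under a fixed seed", {
  cfg <- sim_config(session_duration_s = 60)
  a <- generate_protocol_session(cfg, seed = 7)
  b <- generate_protocol_session(cfg, seed = 7)
  expect_identical(a$recording$acc, b$recording$acc)
  expect_identical(a$labels$turn, b$labels$turn)
  expect_identical(a$episodes, b$episodes)
  dcfg <- daily_config(sampling_rate = 1, n_days = 2, severity = 0.05)
  wa <- generate_week(dcfg, seed = 3)
  wb <- generate_week(dcfg, seed = 3)
  expect_identical(wa$labels$turn, wb$labels$turn)
  expect_identical(wa$bouts, wb$bouts)
  sa <- simulate_detector(a$labels, 2, sampling_rate = 128, seed = 11)
  sb <- simulate_detector(a$labels, 2, sampling_rate = 128, seed = 11)
  expect_identical(sa, sb)
})

test_that("zero trigger probability and non-freezer group emit no FOG", {
  cfg <- sim_config(session_duration_s = 60,
                    fog_trigger_probs = c(turn = 0, walk = 0,
                                          gait_initiation = 0))
  s <- generate_protocol_session(cfg, seed = 2)
  expect_equal(sum(any_fog(s$labels)), 0)
  w <- generate_week(daily_config(sampling_rate = 1, n_days = 2,
                                  group = "non_freezer"), seed = 2)
  expect_equal(sum(any_fog(w$labels)), 0)
  expect_gt(nrow(w$bouts), 0)   # non-freezers still walk
  expect_error(generate_protocol_session(sim_config(session_duration_s = 0)),
               class = "fog_argument_error")
})

test_that("labels are exclusive and FOG stays inside triggering contexts", {
  s <- generate_protocol_session(sim_config(session_duration_s = 240), seed = 5)
  counts <- s$labels$start_hesitation + s$labels$turn + s$labels$walking +
    s$labels$notype
  expect_true(all(counts <= 1))
  # every FOG sample belongs to a segment whose state is a trigger context
  seg <- s$segments
  fog_seg <- seg[!is.na(seg$fog), ]
  expect_true(all(fog_seg$state %in% c("turn", "walk", "gait_initiation")))
  # week-scale: FOG only inside walking bouts
  w <- generate_week(daily_config(sampling_rate = 1, n_days = 2,
                                  severity = 0.15), seed = 8)
  bout_mask <- expand_bouts(w$bouts, pad_s = 0, n = w$labels$n,
                            sampling_rate = 1)
  expect_true(all(bout_mask[any_fog(w$labels)]))
})

test_that("episode counts and durations converge to configured values", {
  cfg <- sim_config(sampling_rate = 32, session_duration_s = 600)
  sessions <- lapply(1:70, function(i) generate_protocol_session(cfg, seed = i))
  eps <- do.call(rbind, lapply(sessions, `[[`, "episodes"))
  visits <- Reduce(`+`, lapply(sessions, `[[`, "context_visits"))
  expect_gte(nrow(eps), 500)
  # per-context trigger rates within 3 binomial SEs of the configuration
  trig <- c(turn = sum(eps$fog_class %in% c("turn", "notype")),
            walk = sum(eps$fog_class == "walking"),
            gait_initiation = sum(eps$fog_class == "start_hesitation"))
  # notype only arises in the defog dialect; default tdcsfog has none
  expect_equal(sum(eps$fog_class == "notype"), 0)
  for (ctx in names(trig)) {
    p <- cfg$fog_trigger_probs[[ctx]]
    se <- sqrt(p * (1 - p) / visits[[ctx]])
    expect_lt(abs(trig[[ctx]] / visits[[ctx]] - p), 3 * se + 1e-9)
  }
  # class shares of episode counts vs the visit-weighted expectation
  expected <- visits * cfg$fog_trigger_probs[names(visits)]
  expected <- expected / sum(expected)
  observed <- trig / sum(trig)
  for (ctx in names(trig)) {
    se <- sqrt(expected[[ctx]] * (1 - expected[[ctx]]) / sum(trig))
    expect_lt(abs(observed[[ctx]] - expected[[ctx]]), 3 * se + 0.01)
  }
  # mean turn-episode duration near the configured 9.7 s
  turn_dur <- eps$duration_s[eps$fog_class == "turn"]
  se_dur <- sd(turn_dur) / sqrt(length(turn_dur))
  expect_lt(abs(mean(turn_dur) - 9.7), 3 * se_dur + 0.2)
})

test_that("synthesized walking has its spectral peak at the step frequency", {
  cfg <- sim_config(noise_sd = 0.02)
  fs <- cfg$sampling_rate
  seg <- data.frame(state = "walk", fog = NA_character_, akinetic = FALSE,
                    n = 20 * fs, end = 20 * fs, start = 0)
  set.seed(61)
  acc <- synthesize_signal(seg, cfg)
  v <- acc[, 1] - mean(acc[, 1])
  spec <- Mod(fft(v))[2:(length(v) %/% 2)]
  peak_hz <- which.max(spec) * fs / length(v)
  expect_lt(abs(peak_hz - cfg$walk_step_freq), 0.2)
})

test_that("akinetic FOG sits at the noise floor, rest is silent without noise", {
  cfg <- sim_config(noise_sd = 0.05)
  fs <- cfg$sampling_rate
  seg <- function(state, fog, akinetic)
    data.frame(state = state, fog = fog, akinetic = akinetic,
               n = 10 * fs, end = 10 * fs, start = 0)
  set.seed(62)
  walk_v <- var(synthesize_signal(seg("walk", NA, FALSE), cfg)[, 1])
  akin_v <- var(synthesize_signal(seg("turn", "turn", TRUE), cfg)[, 1])
  expect_lt(akin_v, 0.1 * walk_v)
  quiet_cfg <- sim_config(noise_sd = 0)
  still <- synthesize_signal(seg("rest", NA, FALSE), quiet_cfg)
  expect_equal(var(still[, 1]), 0)
  expect_equal(unique(still[, 1]), quiet_cfg$gravity)
})

test_that("simulated detector hits the quality limits", {
  set.seed(63)
  lb <- fog_labels(2000, turn = rep(c(FALSE, TRUE), c(1500, 500)))
  perfect <- simulate_detector(lb, quality = 50, sampling_rate = 100, seed = 1)
  expect_equal(average_precision(lb$turn, perfect[, "turn"]), 1)
  aps <- vapply(1:50, function(i) {
    r <- simulate_detector(lb, quality = 0, sampling_rate = 100,
                           noise_corr_s = 0, seed = i)
    average_precision(lb$turn, r[, "turn"])
  }, numeric(1))
  expect_lt(abs(mean(aps) - 0.25), 0.02)   # prevalence 500/2000
  expect_error(simulate_detector(lb, quality = -1),
               class = "fog_argument_error")
})

test_that("weekly FOG intensity peaks where the hourly profile says", {
  # small cohort; the fuller 20-run recovery lives in the acceptance suite
  profs <- lapply(1:8, function(i) {
    cfg <- daily_config(sampling_rate = 1, severity = 0.06)
    w <- generate_week(cfg, seed = 100 + i)
    mask <- expand_bouts(w$bouts, 5, w$labels$n, 1)
    hourly_tf(any_fog(w$labels), mask, cfg$start_clock, 1)
  })
  curve <- colMeans(do.call(rbind, lapply(profs, `[[`, "week_avg")),
                    na.rm = TRUE)
  pk <- sort(profile_peaks(curve))
  expect_true(all(abs(pk - c(7, 22)) <= 1))
})
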