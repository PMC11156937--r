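# Synthetic session / cohort generator. Emulates the statistical structure
# of the FOG-provoking protocol recordings and the week-long 24/7 home
# recordings (class mix, episode durations, akinetic proportions,
# hour-of-day FOG intensity) so that every evaluation stage can be exercised
# without the original competition data. The signal model is deliberately
# spectral rather than biomechanical: walking is a step-frequency
# fundamental plus harmonic, trembling FOG a band-limited oscillation in the
# 3-8 Hz freeze band, akinetic FOG and rest sit at the noise floor.

CONTEXT_CLASS <- c(turn = "turn", walk = "walking",
                   gait_initiation = "start_hesitation")

# lognormal parameterized by its mean and sdlog
rlnorm_mean <- function(n, mean, sdlog) {
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulation configuration for protocol-style sessions
#'
#' Defaults encode the study conditions of the labeled datasets: 128 Hz
#' (m/s^2) for the tDCS-style dialect, 100 Hz (g) for the home-protocol
#' dialect; per-class mean episode durations derived from the event table
#' margins (turn 469.1 min / 2887 events = 9.7 s, start hesitation 15.0 s,
#' walking 5.7 s); akinetic episode proportions 5.6% / 29.3% per dialect;
#' trigger probabilities per context with turns the dominant provoker.
#'
#' @param dialect `"tdcsfog"`, `"defog"` or `"daily"`.
#' @param sampling_rate override of the dialect rate.
#' @param session_duration_s protocol session length.
#' @param fog_trigger_probs probability that entering a context (turn, walk,
#'   gait_initiation) triggers an episode there.
#' @param episode_duration_mean_s per-class mean episode duration (s).
#' @param episode_sdlog lognormal sdlog of episode durations.
#' @param notype_fraction fraction of episodes labeled `notype` (class
#'   withheld).
#' @param akinetic_fraction fraction of episodes rendered akinetic
#'   (noise-floor variance instead of trembling).
#' @param walk_step_freq step frequency (Hz) of simulated gait.
#' @param tremble_band Hz interval of trembling-FOG oscillation.
#' @param noise_sd sensor noise SD (m/s^2).
#' @param hourly_intensity 24-vector multiplying trigger probabilities /
#'   within-bout FOG fractions by clock hour (protocol sessions ignore it).
#' @param group `"freezer"` or `"non_freezer"` (non-freezers emit no FOG).
#' @param severity subject-level within-bout FOG time fraction at intensity
#'   1 (daily dialect).
#' @return list of class `fog_sim_config`.
#' @export
sim_config <- function(dialect = c("tdcsfog", "defog", "daily"),
                       sampling_rate = NULL,
                       session_duration_s = 300,
                       fog_trigger_probs = c(turn = 0.6, walk = 0.15,
                                             gait_initiation = 0.05),
                       episode_duration_mean_s = c(start_hesitation = 15.0,
                                                   turn = 9.7, walking = 5.7),
                       episode_sdlog = 0.6,
                       notype_fraction = NULL,
                       akinetic_fraction = NULL,
                       walk_step_freq = 1.8,
                       tremble_band = c(3, 8),
                       noise_sd = 0.1,
                       hourly_intensity = rep(1, 24),
                       group = c("freezer", "non_freezer"),
                       severity = 0.035) {
  dialect <- match.arg(dialect)
  group <- match.arg(group)
  if (any(fog_trigger_probs < 0 | fog_trigger_probs > 1))
    stop_validation("trigger probabilities must lie in [0, 1]")
  if (any(episode_duration_mean_s <= 0))
    stop_validation("episode durations must be positive")
  if (length(hourly_intensity) != 24L || any(hourly_intensity < 0))
    stop_validation("hourly_intensity must be a non-negative 24-vector")
  structure(list(
    dialect = dialect,
    sampling_rate = sampling_rate %||%
      switch(dialect, tdcsfog = 128, defog = 100, daily = 100),
    session_duration_s = session_duration_s,
    state_dwell = list(stand = c(mean = 8, sdlog = 0.5),
                       walk = c(mean = 15, sdlog = 0.5),
                       turn = c(mean = 2.5, sdlog = 0.3),
                       gait_initiation = c(mean = 1.5, sdlog = 0.3),
                       rest = c(mean = 30, sdlog = 0.6)),
    transitions = list(rest = c(stand = 1),
                       stand = c(gait_initiation = 0.6, rest = 0.4),
                       gait_initiation = c(walk = 1),
                       walk = c(turn = 0.55, stand = 0.35, rest = 0.10),
                       turn = c(walk = 0.8, stand = 0.2)),
    fog_trigger_probs = fog_trigger_probs,
    episode_duration_mean_s = episode_duration_mean_s,
    episode_sdlog = episode_sdlog,
    notype_fraction = notype_fraction %||%
      switch(dialect, tdcsfog = 0, defog = 0.2, daily = 0),
    akinetic_fraction = akinetic_fraction %||%
      switch(dialect, tdcsfog = 0.056, defog = 0.293, daily = 0.293),
    walk_step_freq = walk_step_freq, tremble_band = tremble_band,
    noise_sd = noise_sd, walk_amp = 1.5, turn_amp = 1.0,
    harmonic_ratio = 0.35, gravity = STANDARD_GRAVITY,
    hourly_intensity = hourly_intensity,
    group = group, severity = severity
  ), class = "fog_sim_config")
}

#' Simulation configuration for week-long 24/7 recordings
#'
#' Extends [sim_config] with the daily-living schedule: expected walking
#' bouts and bout durations per clock hour (daytime bouts around 1.5 min,
#' sparse short night bouts — the bathroom-walk motif that keeps the night
#' reference defined), the within-bout FOG class mix dominated by turning,
#' the day-to-day severity jitter, and the hour-of-day FOG intensity profile
#' with its morning (07:00) and late-evening (22:00) peaks. Hours 02:00 and
#' 03:00 have zero FOG intensity, giving a clean no-effect stratum.
#'
#' @inheritParams sim_config
#' @param n_days days to simulate.
#' @param start_clock wall-clock time of the first sample.
#' @param bouts_per_hour expected bout count per clock hour.
#' @param bout_mean_s named c(day, night) mean bout durations.
#' @param class_mix_daily episode-class probabilities in daily living.
#' @param day_sdlog lognormal sdlog of the day-level severity multiplier.
#' @param signal `"auto"` synthesizes the spectral waveform when the
#'   sampling rate resolves the freeze band (>= 32 Hz) and stores zeros
#'   otherwise (label-resolution simulation); `"none"` always stores zeros.
#' @return list of class `fog_sim_config`.
#' @export
daily_config <- function(sampling_rate = 100,
                         group = c("freezer", "non_freezer"),
                         severity = 0.035,
                         n_days = 7,
                         start_clock = as.POSIXct("2024-03-04 00:00:00",
                                                  tz = "UTC"),
                         bouts_per_hour = c(0.4, 0.3, 0.3, 0.3, 0.4, 0.6,
                                            2, 4, 5, 5, 5, 5, 5, 5, 5, 5,
                                            5, 5, 5, 4, 4, 3, 3, 1),
                         bout_mean_s = c(day = 90, night = 25),
                         hourly_intensity = c(0.6, 0.6, 0, 0, 0.6, 0.6,
                                              1.2, 2.0, 1.2, 0.8, 0.8, 0.8,
                                              0.8, 0.8, 0.8, 0.8, 0.8, 0.8,
                                              0.8, 0.8, 0.8, 1.1, 1.8, 0.6),
                         class_mix_daily = c(start_hesitation = 0.005,
                                             turn = 0.94, walking = 0.055),
                         day_sdlog = 0.1,
                         signal = c("auto", "none")) {
  group <- match.arg(group)
  cfg <- sim_config(dialect = "daily", sampling_rate = sampling_rate,
                    hourly_intensity = hourly_intensity, group = group,
                    severity = severity)
  cfg$n_days <- n_days
  cfg$start_clock <- start_clock
  cfg$bouts_per_hour <- bouts_per_hour
  cfg$bout_mean_s <- bout_mean_s
  cfg$class_mix_daily <- class_mix_daily
  cfg$day_sdlog <- day_sdlog
  cfg$signal <- match.arg(signal)
  cfg
}

draw_next_state <- function(trans, state) {
  p <- trans[[state]]
  sample(names(p), 1L, prob = p)
}

#' Generate one labeled protocol-style session
#'
#' Activity states (stand, walk, turn, gait initiation, rest) are drawn from
#' a semi-Markov chain with lognormal dwell times; on entering a triggering
#' context, a FOG episode of the matching class is injected with the
#' configured probability, with lognormal duration, optionally rendered
#' akinetic or labeled `notype`. Labels are mutually exclusive per sample
#' and every FOG sample lies inside its triggering context. Deterministic
#' given `seed`.
#'
#' @param config a [sim_config].
#' @param seed integer seed.
#' @param subject_id,session_id identifiers.
#' @return list: `recording`, `labels`, `episodes` (with `fog_class`,
#'   `akinetic`, `notype`), `segments` (per-segment state bookkeeping),
#'   `context_visits` (named counts of trigger-context entries).
#' @export
generate_protocol_session <- function(config, seed = 1,
                                      subject_id = "s01",
                                      session_id = "sess01") {
  if (config$session_duration_s <= 0)
    stop_argument("session duration must be positive")
  fs <- config$sampling_rate
  with_seed(seed, {
    total <- 0
    state <- "stand"
    seg_state <- character(); seg_dur <- numeric()
    seg_fog <- character(); seg_akinetic <- logical()
    visits <- c(turn = 0L, walk = 0L, gait_initiation = 0L)
    while (total < config$session_duration_s) {
      dw <- config$state_dwell[[state]]
      dur <- rlnorm_mean(1, dw["mean"], dw["sdlog"])
      fog_here <- FALSE
      if (state %in% names(CONTEXT_CLASS)) {
        visits[state] <- visits[state] + 1L
        if (config$group == "freezer" &&
            runif(1) < config$fog_trigger_probs[[state]]) fog_here <- TRUE
      }
      if (fog_here) {
        cls <- CONTEXT_CLASS[[state]]
        ep_dur <- rlnorm_mean(1, config$episode_duration_mean_s[[cls]],
                              config$episode_sdlog)
        lead <- min(dur * runif(1, 0.1, 0.5), 5)
        # context before the episode, the episode, remaining context
        seg_state <- c(seg_state, state, state, state)
        seg_dur <- c(seg_dur, lead, ep_dur, max(dur - lead, 0.5))
        seg_fog <- c(seg_fog, NA_character_,
                     if (runif(1) < config$notype_fraction) "notype" else cls,
                     NA_character_)
        seg_akinetic <- c(seg_akinetic, FALSE,
                          runif(1) < config$akinetic_fraction, FALSE)
        total <- total + lead + ep_dur + max(dur - lead, 0.5)
      } else {
        seg_state <- c(seg_state, state)
        seg_dur <- c(seg_dur, dur)
        seg_fog <- c(seg_fog, NA_character_)
        seg_akinetic <- c(seg_akinetic, FALSE)
        total <- total + dur
      }
      state <- draw_next_state(config$transitions, state)
    }
    n_target <- round(config$session_duration_s * fs)
    seg_n <- pmax(1L, round(seg_dur * fs))
    # trim to the requested length
    cum <- cumsum(seg_n)
    keep <- which(cum - seg_n < n_target)
    seg_n <- seg_n[keep]; seg_state <- seg_state[keep]
    seg_fog <- seg_fog[keep]; seg_akinetic <- seg_akinetic[keep]
    seg_n[length(seg_n)] <- n_target - sum(head(seg_n, -1))
    segments <- data.frame(state = seg_state, fog = seg_fog,
                           akinetic = seg_akinetic, n = seg_n,
                           end = cumsum(seg_n))
    segments$start <- segments$end - segments$n

    n <- n_target
    lab_cls <- rep(NA_character_, n)
    for (i in which(!is.na(segments$fog)))
      lab_cls[(segments$start[i] + 1L):segments$end[i]] <- segments$fog[i]
    labels <- fog_labels(
      n,
      start_hesitation = !is.na(lab_cls) & lab_cls == "start_hesitation",
      turn = !is.na(lab_cls) & lab_cls == "turn",
      walking = !is.na(lab_cls) & lab_cls == "walking",
      notype = !is.na(lab_cls) & lab_cls == "notype"
    )
    acc <- synthesize_signal(segments, config)
    rec <- fog_recording(acc, fs, dialect = config$dialect,
                         subject_id = subject_id, session_id = session_id,
                         units_in = switch(config$dialect, tdcsfog = "m_per_s2", "g"))
    fog_idx <- which(!is.na(segments$fog))
    episodes <- data.frame(fog_class = segments$fog[fog_idx],
                           start = segments$start[fog_idx],
                           end = segments$end[fog_idx],
                           duration_s = segments$n[fog_idx] / fs,
                           akinetic = segments$akinetic[fog_idx],
                           notype = segments$fog[fog_idx] == "notype")
    list(recording = rec, labels = labels, episodes = episodes,
         segments = segments, context_visits = visits)
  })
}

segment_wave <- function(type, t_global, config) {
  f <- config$walk_step_freq
  g <- function(amp, freq, phase = 0)
    amp * sin(2 * pi * freq * t_global + phase)
  switch(type,
    walk = cbind(config$walk_amp * (g(1, f) + config$harmonic_ratio * g(1, 2 * f)),
                 0.5 * config$walk_amp * g(1, f / 2, 0.7),
                 0.6 * config$walk_amp * g(1, f, 1.3)),
    turn = cbind(config$turn_amp * g(1, 0.85 * f),
                 0.7 * config$turn_amp * g(1, 0.85 * f / 2, 0.4),
                 0.5 * config$turn_amp * g(1, 0.85 * f, 1.1)),
    gait_initiation = cbind(0.4 * config$walk_amp * g(1, 0.9 * f),
                            0.25 * config$walk_amp * g(1, 0.45 * f),
                            0.25 * config$walk_amp * g(1, 0.9 * f, 0.9)),
    tremble = {
      fr <- runif(2, config$tremble_band[1] + 0.5, config$tremble_band[2] - 0.5)
      ph <- runif(2, 0, 2 * pi)
      v <- 0.6 * (g(1, fr[1], ph[1]) + g(1, fr[2], ph[2]))
      cbind(v, 0.4 * v, 0.8 * v)
    },
    matrix(0, length(t_global), 3)   # quiet: stand, rest, akinetic FOG
  )
}

#' Synthesize the 3-axis acceleration for a segmented session
#'
#' Walking/turning produce a step-frequency fundamental plus harmonic,
#' trembling FOG a two-component oscillation inside the freeze band,
#' akinetic FOG and rest only the noise floor. Segment waveforms are
#' cosine-tapered at their ends (continuity at state boundaries) before
#' adding white sensor noise and gravity on the vertical axis.
#'
#' @param segments segment table as built by [generate_protocol_session].
#' @param config a [sim_config].
#' @return N x 3 acceleration matrix (m/s^2).
#' @export
synthesize_signal <- function(segments, config) {
  n <- sum(segments$n)
  fs <- config$sampling_rate
  acc <- matrix(0, n, 3)
  for (i in seq_len(nrow(segments))) {
    idx <- (segments$start[i] + 1L):segments$end[i]
    type <- if (!is.na(segments$fog[i])) {
      if (segments$akinetic[i]) "quiet" else "tremble"
    } else segments$state[i]
    w <- segment_wave(type, (idx - 1) / fs, config)
    m <- length(idx)
    ramp_n <- min(max(1L, round(0.2 * fs)), m %/% 4L + 1L)
    env <- rep(1, m)
    if (ramp_n > 1L) {
      r <- 0.5 - 0.5 * cos(pi * (seq_len(ramp_n) - 1) / (ramp_n - 1))
      env[seq_len(ramp_n)] <- r
      env[m - ramp_n + seq_len(ramp_n)] <- rev(r)
    }
    acc[idx, ] <- w * env
  }
  if (config$noise_sd > 0)
    acc <- acc + matrix(rnorm(3 * n, 0, config$noise_sd), n, 3)
  acc[, 1] <- acc[, 1] + config$gravity
  acc
}

place_intervals <- function(n_items, durs, span) {
  # draw non-overlapping intervals inside [0, span); overlapping draws are
  # dropped, keeping placement simple and unbiased for sparse occupancy
  if (n_items == 0L) return(cbind(start = numeric(), end = numeric()))
  starts <- runif(n_items, 0, pmax(span - durs, 0))
  o <- order(starts)
  starts <- starts[o]; durs <- durs[o]
  out_s <- numeric(); out_e <- numeric(); last_end <- -Inf
  for (i in seq_len(n_items)) {
    if (starts[i] >= last_end && starts[i] + durs[i] <= span) {
      out_s <- c(out_s, starts[i]); out_e <- c(out_e, starts[i] + durs[i])
      last_end <- starts[i] + durs[i]
    }
  }
  cbind(start = out_s, end = out_e)
}

#' Generate a week-long 24/7 recording with ground-truth bouts
#'
#' Walking bouts are placed per clock hour following the configured bout
#' schedule (dense daytime walking, sparse short night bouts); within each
#' bout, FOG episodes are injected so that the expected within-bout FOG
#' fraction equals `severity * hourly_intensity[hour]` (damped by a
#' day-level lognormal multiplier), with class drawn from the daily-living
#' mix. Non-freezers emit zero FOG. Deterministic given `seed`.
#'
#' @param config a [daily_config].
#' @param seed integer seed.
#' @param subject_id identifier.
#' @return list: `recording` (dialect `daily`), `labels`, `bouts`
#'   (data.frame of half-open sample intervals), `episodes`.
#' @export
generate_week <- function(config, seed = 1, subject_id = "s01") {
  if (is.null(config$start_clock)) stop_argument("start_clock must be set")
  fs <- config$sampling_rate
  n <- round(config$n_days * 86400 * fs)
  mean_ep <- sum(config$class_mix_daily *
                   config$episode_duration_mean_s[names(config$class_mix_daily)])
  with_seed(seed, {
    cls_code <- integer(n)   # 0 none, 1 start_hesitation, 2 turn, 3 walking
    bout_s <- numeric(); bout_e <- numeric()
    ep_rows <- list()
    for (d in seq_len(config$n_days) - 1L) {
      day_mult <- rlnorm_mean(1, 1, config$day_sdlog)
      for (h in 0:23) {
        nb <- rpois(1, config$bouts_per_hour[h + 1L])
        if (nb == 0L) next
        night <- h >= 23 || h <= 5
        durs <- rlnorm_mean(nb, config$bout_mean_s[[if (night) "night" else "day"]], 0.5)
        durs <- pmin(durs, 3300)
        iv <- place_intervals(nb, durs, 3600)
        if (!nrow(iv)) next
        hour_off <- (d * 86400 + h * 3600)
        for (b in seq_len(nrow(iv))) {
          b0 <- round((hour_off + iv[b, 1]) * fs)
          b1 <- round((hour_off + iv[b, 2]) * fs)
          if (b1 <= b0) next
          bout_s <- c(bout_s, b0); bout_e <- c(bout_e, b1)
          if (config$group == "non_freezer") next
          frac <- min(0.8, config$severity * day_mult *
                        config$hourly_intensity[h + 1L])
          if (frac <= 0) next
          span <- (b1 - b0) / fs
          n_ep <- rpois(1, frac * span / mean_ep)
          if (n_ep == 0L) next
          k <- sample(names(config$class_mix_daily), n_ep, replace = TRUE,
                      prob = config$class_mix_daily)
          ed <- rlnorm_mean(n_ep, 1, config$episode_sdlog) *
            config$episode_duration_mean_s[k]
          epi <- place_intervals(n_ep, pmin(ed, span), span)
          for (e in seq_len(nrow(epi))) {
            e0 <- b0 + round(epi[e, 1] * fs); e1 <- b0 + round(epi[e, 2] * fs)
            if (e1 <= e0) next
            cls_code[(e0 + 1L):e1] <- match(k[e], FOG_CLASSES)
            ep_rows[[length(ep_rows) + 1L]] <-
              data.frame(fog_class = k[e], start = e0, end = e1,
                         duration_s = (e1 - e0) / fs)
          }
        }
      }
    }
    labels <- fog_labels(
      n,
      start_hesitation = cls_code == 1L,
      turn = cls_code == 2L,
      walking = cls_code == 3L
    )
    want_signal <- !identical(config$signal %||% "auto", "none") && fs >= 32
    acc <- if (want_signal) {
      segs <- data.frame(state = "rest", fog = NA_character_,
                         akinetic = FALSE, n = n, end = n, start = 0)
      synthesize_signal(segs, config)   # quiet floor; bouts not re-rendered
    } else matrix(0, n, 3)
    rec <- fog_recording(acc, fs, dialect = "daily",
                         subject_id = subject_id, session_id = "week01",
                         start_clock = config$start_clock, units_in = "g")
    bouts <- data.frame(start = bout_s, end = bout_e)
    bouts <- bouts[order(bouts$start), , drop = FALSE]
    episodes <- if (length(ep_rows)) do.call(rbind, ep_rows)
                else data.frame(fog_class = character(), start = integer(),
                                end = integer(), duration_s = numeric())
    list(recording = rec, labels = labels, bouts = bouts, episodes = episodes)
  })
}

#' Generate a daily-living cohort manifest with an injected group effect
#'
#' Subject severities (within-bout FOG fraction at unit intensity) are drawn
#' from a gamma distribution whose coefficient of variation is solved from
#' the requested pooled-SD standardized effect: non-freezers emit zero FOG
#' (zero variance), so for group sizes `n_f`, `n_nf` the population Cohen's
#' d of mean %TF is `mean / (sd * sqrt((n_f - 1) / (n_f + n_nf - 2)))`, and
#' the generator sets `cv = 1 / (d * sqrt((n_f - 1) / (n_f + n_nf - 2)))`.
#' NFOG-Q scores are assigned rank-monotonically in severity on the 11-28
#' range so the cohort median lands at the questionnaire cutoff of 20.
#'
#' @param n_freezers,n_nonfreezers group sizes (defaults 45 / 19).
#' @param effect_d injected standardized daily-%TF difference.
#' @param mean_tf mean freezer severity (within-bout FOG fraction).
#' @param seed integer seed.
#' @return data.frame manifest: `subject_id`, `group`, `severity`, `nfogq`.
#' @export
generate_cohort <- function(n_freezers = 45, n_nonfreezers = 19,
                            effect_d = 0.7, mean_tf = 0.035, seed = 1) {
  stopifnot(n_freezers >= 2, n_nonfreezers >= 2)
  cv <- 1 / (effect_d * sqrt((n_freezers - 1) / (n_freezers + n_nonfreezers - 2)))
  shape <- 1 / cv^2
  with_seed(seed, {
    sev <- rgamma(n_freezers, shape = shape, scale = mean_tf / shape)
    r <- rank(sev, ties.method = "first")
    nfogq <- round(11 + 17 * (r - 1) / (n_freezers - 1))
    data.frame(
      subject_id = c(sprintf("F%02d", seq_len(n_freezers)),
                     sprintf("C%02d", seq_len(n_nonfreezers))),
      group = rep(c("freezer", "non_freezer"), c(n_freezers, n_nonfreezers)),
      severity = c(sev, rep(0, n_nonfreezers)),
      nfogq = c(nfogq, rep(0L, n_nonfreezers))
    )
  })
}

#' Simulate a per-sample confidence detector of controllable quality
#'
#' Per class, the ground-truth indicator is corrupted by shifting episode
#' boundaries with Gaussian jitter and inserting false-positive bursts at
#' `fp_rate` per minute, then scored as
#' `plogis(quality * indicator + noise)`, where the unit-variance noise is
#' temporally smoothed over `noise_corr_s` seconds — real per-sample
#' confidences are autocorrelated, and white noise would shred decision
#' runs into implausible one-sample episodes. `quality = 0` is an
#' uninformative detector (AP equals class prevalence in expectation);
#' quality increasing without bound approaches perfect ranking.
#' Deterministic given `seed`.
#'
#' @param labels a [fog_labels].
#' @param quality non-negative signal-to-noise parameter.
#' @param fp_rate false-positive bursts per minute.
#' @param boundary_jitter_s SD of the boundary shift (s).
#' @param sampling_rate Hz.
#' @param noise_corr_s correlation window of the score noise (s).
#' @param seed integer seed.
#' @return N x 3 score matrix.
#' @export
simulate_detector <- function(labels, quality, fp_rate = 0,
                              boundary_jitter_s = 0, sampling_rate = 100,
                              noise_corr_s = 2, seed = 1) {
  if (!is.numeric(quality) || quality < 0)
    stop_argument("quality must be a non-negative real")
  n <- labels$n
  with_seed(seed, {
    out <- matrix(NA_real_, n, 3)
    for (j in seq_along(FOG_CLASSES)) {
      ind <- labels[[FOG_CLASSES[j]]]
      if (boundary_jitter_s > 0 && any(ind)) {
        eps <- extract_episodes(ind, sampling_rate)
        ind <- logical(n)
        for (i in seq_len(nrow(eps))) {
          s <- eps$start[i] + round(rnorm(1, 0, boundary_jitter_s * sampling_rate))
          e <- eps$end[i] + round(rnorm(1, 0, boundary_jitter_s * sampling_rate))
          s <- max(0L, s); e <- min(n, max(e, s + 1L))
          ind[(s + 1L):e] <- TRUE
        }
      }
      if (fp_rate > 0) {
        n_fp <- rpois(1, fp_rate * n / sampling_rate / 60)
        if (n_fp > 0) {
          durs <- round(rlnorm_mean(n_fp, 2, 0.5) * sampling_rate)
          starts <- sample.int(n, n_fp, replace = TRUE)
          for (i in seq_len(n_fp)) {
            e <- min(n, starts[i] + durs[i])
            ind[starts[i]:e] <- TRUE
          }
        }
      }
      w <- max(1L, round(noise_corr_s * sampling_rate))
      noise <- rnorm(n)
      if (w > 1L)   # moving sum / sqrt(w): unit variance, w-sample memory
        noise <- as.numeric(stats::filter(noise, rep(1, w) / sqrt(w),
                                          sides = 2, circular = TRUE))
      out[, j] <- plogis(quality * ind + noise)
    }
    fog_scores(out)
  })
}
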