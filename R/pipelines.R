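# Orchestration: the two end-to-end pipelines (test-set evaluation and
# daily-living analysis), a streaming cohort simulator, and machine-readable
# report output with a provenance block.

fail_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    fog_error("fog_stage_error",
              sprintf("stage '%s' failed: %s", stage, conditionMessage(e))))
}

provenance <- function(seed = NULL) {
  list(package = "fogbench",
       version = as.character(utils::packageVersion("fogbench")),
       seed = seed)
}

write_report <- function(report, out_dir, name, seed = NULL) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report$provenance <- provenance(seed)
  jsonlite::write_json(report, file.path(out_dir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  invisible(file.path(out_dir, paste0(name, ".json")))
}

# pool a list of per-session label series into one long series
concat_labels <- function(labels_list) {
  pull <- function(f) unlist(lapply(labels_list, `[[`, f), use.names = FALSE)
  fog_labels(sum(vapply(labels_list, `[[`, numeric(1), "n")),
             start_hesitation = pull("start_hesitation"), turn = pull("turn"),
             walking = pull("walking"), notype = pull("notype"),
             valid = pull("valid"), task = pull("task"))
}

#' Test-set evaluation pipeline
#'
#' Runs the full protocol-data evaluation over a set of labeled sessions and
#' aligned score series: competition mAP (pooled per-class AP), all-FOG ROC
#' AUC, the operating-point metric table, per-subject gold-standard outcome
#' pairs (truth vs estimate at the all-FOG operating point), and the ICC(2,1)
#' agreement between them. Deterministic given inputs; stage failures abort
#' with the stage name.
#'
#' @param sessions list of session objects (`recording`, `labels`), e.g.
#'   from [generate_protocol_session] or [read_recording].
#' @param scores_list aligned list of score matrices; `NULL` scores every
#'   session with the freeze-index baseline ([baseline_scores]).
#' @param merge_gap_s,min_duration_s optional post-processing of the
#'   *estimated* decision series before episode extraction (defaults off;
#'   ground-truth episodes are never post-processed).
#' @param out_dir optional directory for a JSON report.
#' @param seed recorded in the report's provenance block (the pipeline
#'   itself draws no randomness).
#' @return list: `per_class_ap`, `mAP`, `all_fog_auc`, `operating_points`,
#'   `subjects`, `icc`.
#' @export
run_eval_pipeline <- function(sessions, scores_list = NULL,
                              merge_gap_s = 0, min_duration_s = 0,
                              out_dir = NULL, seed = NULL) {
  if (!length(sessions)) stop_argument("no sessions supplied")
  labels_list <- lapply(sessions, `[[`, "labels")
  if (is.null(scores_list))
    scores_list <- fail_stage("baseline_scores",
      lapply(sessions, function(s) baseline_scores(s$recording)))
  if (length(scores_list) != length(sessions))
    stop_argument("missing submission: scores_list does not cover the sessions")
  masks <- lapply(labels_list, make_mask)

  map_res <- fail_stage("scoring",
    mean_average_precision(labels_list, scores_list, masks))

  pooled_labels <- concat_labels(labels_list)
  pooled_scores <- fog_scores(do.call(rbind, scores_list))
  pooled_mask <- unlist(masks, use.names = FALSE)
  bin <- binarize_all_fog(pooled_labels, pooled_scores)
  roc <- fail_stage("roc", roc_curve(bin$labels, bin$scores, pooled_mask))
  op <- fail_stage("operating_point",
    operating_point_metrics(pooled_labels, pooled_scores, pooled_mask))
  thr <- op$threshold[op$fog_class == "all_fog"]

  subj <- fail_stage("subject_summaries", {
    ids <- vapply(sessions, function(s) s$recording$subject_id, character(1))
    rows <- lapply(unique(ids), function(id) {
      sel <- which(ids == id)
      fs <- sessions[[sel[1]]]$recording$sampling_rate
      lab <- concat_labels(labels_list[sel])
      msk <- unlist(masks[sel], use.names = FALSE)
      sc <- do.call(rbind, scores_list[sel])
      b <- binarize_all_fog(lab, fog_scores(sc))
      truth <- subject_summary(extract_episodes(b$labels, fs), msk, fs, id)
      est <- subject_summary(extract_episodes(b$scores >= thr, fs,
                                              min_duration_s = min_duration_s,
                                              merge_gap_s = merge_gap_s),
                             msk, fs, id)
      names(est) <- paste0("est_", names(est))
      cbind(truth, est[-1])
    })
    do.call(rbind, rows)
  })

  icc <- NULL
  if (nrow(subj) >= 3L) {
    icc <- fail_stage("agreement", list(
      percent_time_frozen = icc_2_1(cbind(subj$percent_time_frozen,
                                          subj$est_percent_time_frozen)),
      n_episodes = icc_2_1(cbind(subj$n_episodes, subj$est_n_episodes)),
      total_duration_s = icc_2_1(cbind(subj$total_duration_s,
                                       subj$est_total_duration_s))))
  } else warning("fewer than 3 subjects: ICC agreement skipped")

  out <- list(per_class_ap = map_res$per_class, mAP = map_res$mAP,
              all_fog_auc = auc(roc), all_fog_threshold = thr,
              operating_points = op, subjects = subj, icc = icc)
  write_report(list(per_class_ap = as.list(map_res$per_class),
                    mAP = map_res$mAP, all_fog_auc = auc(roc),
                    operating_points = op),
               out_dir, "eval_report", seed)
  out
}

#' Simulate a daily-living cohort into hourly profiles
#'
#' Streams the week-long simulation subject by subject (generating each
#' subject's recording, padding its ground-truth bouts by 5 s, and reducing
#' immediately to an hourly profile and class time shares) so cohort-scale
#' experiments stay in constant memory. Each subject draws its own
#' reproducible substream from `(seed, subject_id)`.
#'
#' @param n_freezers,n_nonfreezers group sizes.
#' @param effect_d injected standardized daily-%TF group difference.
#' @param seed integer seed.
#' @param sampling_rate simulation rate in Hz; hourly/daily %TF are
#'   sampling-rate invariant, so label-resolution cohorts default to 1 Hz.
#' @param mean_tf mean freezer severity.
#' @param pad_s bout padding in seconds.
#' @return list of class `fog_daily_cohort`: `manifest`, `profiles` (named
#'   list of `fog_hourly_profile`), `shares` (subjects x 3 class shares).
#' @export
simulate_daily_cohort <- function(n_freezers = 45, n_nonfreezers = 19,
                                  effect_d = 0.7, seed = 1,
                                  sampling_rate = 1, mean_tf = 0.035,
                                  pad_s = 5) {
  manifest <- generate_cohort(n_freezers, n_nonfreezers, effect_d, mean_tf,
                              seed = substream_seed(seed, "cohort"))
  profiles <- list(); shares <- matrix(NA_real_, nrow(manifest), 3,
                                       dimnames = list(manifest$subject_id,
                                                       FOG_CLASSES))
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$subject_id[i]
    cfg <- daily_config(sampling_rate = sampling_rate,
                        group = manifest$group[i],
                        severity = manifest$severity[i], signal = "none")
    wk <- generate_week(cfg, seed = substream_seed(seed, id), subject_id = id)
    mask <- expand_bouts(wk$bouts, pad_s = pad_s, n = wk$labels$n,
                         sampling_rate = sampling_rate)
    profiles[[id]] <- hourly_tf(any_fog(wk$labels), mask, cfg$start_clock,
                                sampling_rate, subject_id = id)
    sh <- class_time_shares(cbind(wk$labels$start_hesitation,
                                  wk$labels$turn, wk$labels$walking))
    shares[i, ] <- as.numeric(sh)
  }
  structure(list(manifest = manifest, profiles = profiles, shares = shares,
                 sampling_rate = sampling_rate, seed = seed),
            class = "fog_daily_cohort")
}

#' Daily-living analysis pipeline
#'
#' From per-subject hourly profiles and the cohort manifest: per-hour
#' freezer-vs-non-freezer Mann-Whitney comparison with BKY adjustment, the
#' daytime-vs-night-reference Friedman analysis for freezers, the NFOG-Q
#' severity split with its Friedman/Dunn comparison, day-to-day stability
#' (ICC(A,k) of daily %TF over the first `icc_days` days), the daily-%TF
#' group effect size, and (when paired protocol shares are supplied) the
#' per-class protocol-vs-daily Wilcoxon comparison.
#'
#' @param cohort a `fog_daily_cohort` (see [simulate_daily_cohort]), or any
#'   list with `manifest` and `profiles`.
#' @param q FDR level.
#' @param daytime daytime clock hours.
#' @param icc_days number of leading days for the stability ICC.
#' @param protocol_shares optional freezer protocol class-share matrix
#'   paired with the cohort's daily shares.
#' @param out_dir optional directory for a JSON report.
#' @return list of analysis results (see Details).
#' @export
run_daily_pipeline <- function(cohort, q = 0.05, daytime = 7:22,
                               icc_days = 6, protocol_shares = NULL,
                               out_dir = NULL) {
  manifest <- cohort$manifest
  profiles <- cohort$profiles[manifest$subject_id]
  fr <- manifest$group == "freezer"
  freezer_profiles <- profiles[fr]
  nonfreezer_profiles <- profiles[!fr]

  out <- list()
  out$freezer_week_avg <- colMeans(profiles_to_matrix(freezer_profiles),
                                   na.rm = TRUE)
  out$nonfreezer_week_avg <- if (any(!fr))
    colMeans(profiles_to_matrix(nonfreezer_profiles), na.rm = TRUE)

  if (sum(fr) < 2L || sum(!fr) < 2L) {
    warning("need two subjects per group: group statistics skipped")
    return(out)
  }

  out$group_comparison <- fail_stage("group_comparison",
    compare_groups_hourly(freezer_profiles, nonfreezer_profiles, q = q))

  out$daytime_vs_night <- tryCatch(
    daytime_vs_night(freezer_profiles, daytime = daytime, q = q),
    fog_insufficient_data_error = function(e) { warning(conditionMessage(e)); NULL })

  sev_manifest <- fail_stage("severity_split", severity_split(manifest))
  out$severity_cutoff <- attr(sev_manifest, "cutoff")
  grp <- split(sev_manifest$subject_id, sev_manifest$severity_group)
  if (all(c("non_freezer", "moderate", "severe") %in% names(grp))) {
    out$severity_comparison <- fail_stage("severity_comparison",
      severity_comparison(list(non_freezer = profiles[grp$non_freezer],
                               moderate = profiles[grp$moderate],
                               severe = profiles[grp$severe]),
                          daytime = daytime, q = q))
  }

  daily_mean <- vapply(profiles, function(p) mean(p$daily, na.rm = TRUE),
                       numeric(1))
  out$daily_tf <- data.frame(subject_id = manifest$subject_id,
                             group = manifest$group,
                             daily_tf = unname(daily_mean))
  out$cohens_d_daily_tf <- fail_stage("effect_size",
    cohens_d(daily_mean[fr], daily_mean[!fr]))

  day_mat <- do.call(rbind, lapply(freezer_profiles, function(p)
    p$daily[seq_len(icc_days)]))
  complete <- stats::complete.cases(day_mat)
  out$icc_daily_tf <- if (sum(complete) >= 3L)
    fail_stage("daily_icc", icc_a_k(day_mat[complete, , drop = FALSE]))

  if (!is.null(protocol_shares)) {
    daily_shares <- cohort$shares[fr, , drop = FALSE]
    keep <- stats::complete.cases(daily_shares) &
      stats::complete.cases(protocol_shares)
    out$class_distribution <- fail_stage("class_distribution",
      class_distribution_comparison(protocol_shares[keep, , drop = FALSE],
                                    daily_shares[keep, , drop = FALSE]))
  }

  write_report(list(
    freezer_week_avg = out$freezer_week_avg,
    nonfreezer_week_avg = out$nonfreezer_week_avg,
    group_comparison = out$group_comparison,
    cohens_d_daily_tf = out$cohens_d_daily_tf,
    severity_cutoff = out$severity_cutoff),
    out_dir, "daily_report", cohort$seed %||% NULL)
  out
}
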