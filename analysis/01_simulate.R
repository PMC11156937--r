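#!/usr/bin/env Rscript
# Simulate a labeled protocol test set and a per-sample confidence
# submission for it. Writes a handful of session CSVs in the competition
# dialects plus the submission file under results/simulated/.

suppressPackageStartupMessages(library(fogbench))

seed <- 20240301
out <- "results/simulated"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# 20 sessions from 10 subjects, two per subject, default study conditions
sessions <- lapply(1:20, function(i)
  generate_protocol_session(sim_config(), seed = seed + i,
                            subject_id = sprintf("s%02d", (i + 1) %/% 2),
                            session_id = sprintf("sess%02d", i)))
scores <- lapply(seq_along(sessions), function(i)
  simulate_detector(sessions[[i]]$labels, quality = 3.5, fp_rate = 0.2,
                    boundary_jitter_s = 0.2, sampling_rate = 128,
                    seed = seed + 1000 + i))
names(scores) <- vapply(sessions, function(s) s$recording$session_id,
                        character(1))

# persist a few sessions in the on-disk dialect and the full submission
for (i in 1:3)
  write_recording(sessions[[i]]$recording, sessions[[i]]$labels,
                  file.path(out, sprintf("tdcsfog_sess%02d.csv", i)))
write_submission(scores, file.path(out, "submission.csv"))
jsonlite::write_json(list(seed = seed, n_sessions = length(sessions)),
                     file.path(out, "provenance.json"), auto_unbox = TRUE)

ep <- do.call(rbind, lapply(sessions, `[[`, "episodes"))
cat(sprintf("simulated %d sessions, %d FOG episodes (%.1f min total FOG)\n",
            length(sessions), nrow(ep), sum(ep$duration_s) / 60))
cat(sprintf("class mix: %s\n",
            paste(names(table(ep$fog_class)), table(ep$fog_class),
                  sep = "=", collapse = ", ")))
cat("wrote", file.path(out, "submission.csv"), "\n")
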