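#!/usr/bin/env Rscript
# How do the evaluation metrics respond to detector quality? Sweeps the
# simulated detector's signal-to-noise parameter and tabulates all-FOG AP,
# F1 at the PR-optimal threshold, and ROC AUC. Writes results/quality/.

suppressPackageStartupMessages(library(fogbench))

seed <- 20240302
out <- "results/quality"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

s <- generate_protocol_session(sim_config(sampling_rate = 64,
                                          session_duration_s = 300),
                               seed = seed)
qualities <- seq(0, 5, by = 0.5)
# common random numbers: one noise realization re-scored at every quality,
# so the table shows the effect of the quality dial alone
tab <- do.call(rbind, lapply(seq_along(qualities), function(j) {
  sc <- simulate_detector(s$labels, qualities[j], sampling_rate = 64,
                          seed = seed + 1)
  b <- binarize_all_fog(s$labels, sc)
  thr <- select_threshold(pr_curve(b$labels, b$scores))
  data.frame(quality = qualities[j],
             ap = average_precision(b$labels, b$scores),
             f1 = confusion_metrics(b$labels, b$scores >= thr)$f1,
             auc = auc(roc_curve(b$labels, b$scores)))
}))
print(tab, digits = 3)
cat(sprintf("\nSpearman rank correlation with quality: AP %.3f, F1 %.3f\n",
            cor(tab$quality, tab$ap, method = "spearman"),
            cor(tab$quality, tab$f1, method = "spearman")))
utils::write.csv(tab, file.path(out, "quality_sweep.csv"), row.names = FALSE)
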