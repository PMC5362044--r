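#!/usr/bin/env Rscript
# Step 3: Information-Gain selection and cross-validated classification.
#
# For each preset: five-fold nested evaluation (selection re-run inside
# every training fold) with Gaussian Naive Bayes, scored by micro-average
# accuracy against the ZeroR majority baseline with a paired t-test.
# Writes per-preset ig_ranking.csv and report.json under
# results/comparisons/<preset>/ and prints a summary table.

suppressMessages(library(stylemark))
seed <- 20260929 %% 10000L

summary_rows <- list()
for (preset in c("A", "B", "C", "D", "E", "F")) {
  feats <- read.csv(file.path("results", paste0("features_", preset, ".csv")),
                    stringsAsFactors = FALSE)
  cfg <- run_config(seed = seed + match(preset, LETTERS))
  ev <- cross_validate(feats, cfg$classifier, cfg$n_folds, cfg$seed)
  out_dir <- file.path("results", "comparisons", preset)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rk <- do.call(rbind, lapply(seq_along(ev$rankings), function(f)
    cbind(fold = f, ev$rankings[[f]]$ranking)))
  write.csv(rk, file.path(out_dir, "ig_ranking.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(classifier = ev$classifier, micro_accuracy = ev$micro_accuracy,
         baseline_accuracy = ev$baseline_accuracy, p_value = ev$p_value,
         n_selected_per_fold = ev$n_selected, seed = cfg$seed),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  summary_rows[[preset]] <- data.frame(
    preset = preset, accuracy = round(ev$micro_accuracy, 3),
    baseline = round(ev$baseline_accuracy, 3),
    p_value = signif(ev$p_value, 3),
    mean_selected = mean(ev$n_selected))
}
summary_df <- do.call(rbind, summary_rows)
write.csv(summary_df, file.path("results", "classification_summary.csv"),
          row.names = FALSE)
print(summary_df, row.names = FALSE)
cat("\nContrasts involving the repetitive (manic-style) period should beat",
    "the baseline;\nthe style-identical null contrasts E and F should not.\n")
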