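#!/usr/bin/env Rscript
# Step 2: extract the 29-feature matrix for every simulated corpus.
#
# Letters are reloaded from disk (metadata + text files), tokenized and
# segmented; POS tags and production-unit counts come from the ground truth
# written beside each corpus. One features.csv per preset, one row per
# letter: id, period, then the 29 features in canonical order.

suppressMessages(library(stylemark))

for (preset in c("A", "B", "C", "D", "E", "F")) {
  dir <- file.path("results", "corpora", preset)
  corpus <- load_corpus(dir, file.path(dir, "metadata.csv"))
  gt <- load_ground_truth(file.path(dir, "ground_truth.json"))
  feats <- extract_features(corpus, run_config(), tags = gt$tags,
                            counts = gt$counts)
  out <- file.path("results", paste0("features_", preset, ".csv"))
  write.csv(feats, out, row.names = FALSE)
  cat(sprintf("preset %s: %d letters x %d features -> %s\n", preset,
              nrow(feats), length(feature_names()), out))
}
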