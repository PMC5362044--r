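# Pipeline orchestration: configuration, feature-matrix extraction, the
# two-period comparison (extract -> select -> classify -> report) and the
# within-period stability analysis.

#' Run configuration with the pipeline defaults
#'
#' All thresholds are surfaced as named, defaulted options; any override is
#' recorded in the report.
#'
#' @param classifier `"nb"` (default) or `"mlp"`.
#' @param dialect Sentence-segmentation dialect (default `"modern"`).
#' @param block_size Segmental block size in tokens (default 10).
#' @param n_folds Cross-validation folds (default 5).
#' @param alpha Significance level for the classifier-vs-baseline t-test
#'   (default 0.05).
#' @param stability_threshold Corrected ANOVA threshold (default 0.001).
#' @param seed Integer seed for fold assignment and MLP training.
#' @return List of class `run_config`.
#' @export
run_config <- function(classifier = "nb", dialect = "modern",
                       block_size = 10L, n_folds = 5L, alpha = 0.05,
                       stability_threshold = 0.001, seed = 1L) {
  stopifnot(classifier %in% c("nb", "mlp"),
            dialect %in% c("modern", "historical"),
            block_size >= 2L, n_folds >= 2L,
            alpha > 0, alpha < 1, stability_threshold > 0)
  structure(list(classifier = classifier, dialect = dialect,
                 block_size = as.integer(block_size),
                 n_folds = as.integer(n_folds), alpha = alpha,
                 stability_threshold = stability_threshold,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Extract the 29-feature matrix for a corpus
#'
#' Tokenizes, segments and tags every letter, obtains parse counts (ground
#' truth when available, otherwise parsed trees), and assembles the
#' feature matrix: one row per letter with columns `id`, `period` and the
#' 29 features in canonical order.
#'
#' @param corpus data.frame of letters ([load_corpus()]) or a
#'   `synthetic_corpus` (then ground-truth tags and counts are used).
#' @param config A [run_config()].
#' @param tags Optional named list of ground-truth tag vectors by id.
#' @param counts Optional named list of `parse_counts` by id.
#' @param trees Optional named list (by id) of per-sentence bracketed trees.
#' @param backend POS backend passed to [pos_tag()] when no tags given.
#' @return data.frame: `id`, `period`, then [feature_names()].
#' @export
extract_features <- function(corpus, config = run_config(), tags = NULL,
                             counts = NULL, trees = NULL,
                             backend = "rules") {
  if (inherits(corpus, "synthetic_corpus")) {
    tags <- corpus$tags
    counts <- corpus$counts
    corpus <- corpus$corpus
  }
  rows <- lapply(seq_len(nrow(corpus)), function(i) {
    id <- corpus$id[i]
    tl <- tokenize_letter(corpus[i, ], dialect = config$dialect)
    tl <- pos_tag(tl, backend = backend,
                  tags = if (!is.null(tags)) tags[[id]] else NULL)
    pc <- letter_parse_counts(tl,
                              trees = if (!is.null(trees)) trees[[id]] else NULL,
                              ground_truth = if (!is.null(counts)) counts[[id]] else NULL)
    feats <- c(syntactic_ratios(pc), textual_profile(tl, corpus$text[i]))
    cbind(data.frame(id = id, period = corpus$period[i],
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(feats[feature_names()])))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run a full two-period comparison
#'
#' The three-stage analysis on one corpus: feature extraction, per-fold
#' Information-Gain selection, and cross-validated classification against
#' the ZeroR baseline. When `out_dir` is given, writes the feature matrix
#' (`features.csv`), the per-fold IG rankings (`ig_ranking.csv`, columns
#' fold/rank/feature/ig) and the report (`report.json`, mirroring the
#' per-class correct/incorrect, micro accuracy, baseline and p-value
#' layout, plus the configuration and seed).
#'
#' @param corpus Corpus data.frame or `synthetic_corpus`.
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @param ... Passed to [extract_features()] (tags, counts, trees, backend).
#' @return List of class `comparison_report`: `features`, `evaluation`
#'   (an `evaluation_result`), `ig_rankings` (long data.frame), `config`.
#' @export
run_comparison <- function(corpus, config = run_config(), out_dir = NULL,
                           ...) {
  features <- extract_features(corpus, config, ...)
  ev <- cross_validate(features, classifier = config$classifier,
                       n_folds = config$n_folds, seed = config$seed)
  rk <- do.call(rbind, lapply(seq_along(ev$rankings), function(f)
    cbind(fold = f, ev$rankings[[f]]$ranking)))
  report <- structure(list(features = features, evaluation = ev,
                           ig_rankings = rk, config = config),
                      class = "comparison_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(features, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    utils::write.csv(rk, file.path(out_dir, "ig_ranking.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' Plain-list form of a comparison report (for JSON serialization)
#'
#' @param report A `comparison_report`.
#' @return Nested list mirroring the published confusion-table layout.
#' @export
report_json <- function(report) {
  ev <- report$evaluation
  list(classifier = ev$classifier,
       classes = as.list(stats::setNames(
         lapply(seq_len(nrow(ev$counts)), function(i)
           list(correct = ev$counts$correct[i],
                incorrect = ev$counts$incorrect[i])),
         ev$counts$class)),
       micro_accuracy = ev$micro_accuracy,
       baseline_accuracy = ev$baseline_accuracy,
       p_value = ev$p_value,
       fold_accuracy = ev$fold_accuracy,
       baseline_fold_accuracy = ev$baseline_fold_accuracy,
       n_selected_per_fold = ev$n_selected,
       significant_vs_baseline = ev$p_value < report$config$alpha &&
         ev$micro_accuracy > ev$baseline_accuracy,
       config = unclass(report$config))
}

#' @export
print.comparison_report <- function(x, ...) {
  print(x$evaluation)
  invisible(x)
}

#' Run the within-period stability analysis
#'
#' Restricts the corpus to one period, splits it into three chronological
#' epochs and tests all 29 features with one-way ANOVAs. When `out_dir` is
#' given, writes `stability.csv` (feature, per-epoch mean (sd), p,
#' significance).
#'
#' @param corpus Corpus data.frame or `synthetic_corpus`.
#' @param period Period label to analyze.
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @param ... Passed to [extract_features()].
#' @return A `stability_result` (see [stability_anova()]).
#' @export
run_stability <- function(corpus, period, config = run_config(),
                          out_dir = NULL, ...) {
  syn <- inherits(corpus, "synthetic_corpus")
  letters_df <- if (syn) corpus$corpus else corpus
  keep <- letters_df$period == period
  if (!any(keep)) stop("no letters with period '", period, "'")
  sub <- letters_df[keep, , drop = FALSE]
  if (syn) {
    corpus_sub <- structure(list(corpus = sub,
                                 tags = corpus$tags[sub$id],
                                 counts = corpus$counts[sub$id]),
                            class = "synthetic_corpus")
  } else {
    corpus_sub <- sub
  }
  feats <- extract_features(corpus_sub, config, ...)
  feats <- feats[match(sub$id, feats$id), , drop = FALSE]
  epochs <- split_epochs(sub)
  res <- stability_anova(feats, epochs,
                         threshold = config$stability_threshold)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(res),
                     file.path(out_dir, "stability.csv"), row.names = FALSE)
  }
  res
}
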