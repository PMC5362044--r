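# Nested five-fold cross-validation: Information-Gain selection is re-run
# inside every training fold (never on the full data), the classifier is
# trained on the same four folds restricted to the selected features, and
# the held-out fold is scored; fold confusion counts are pooled into the
# micro-average accuracy and compared with the ZeroR baseline by a paired
# t-test over the per-fold accuracies.

#' Seeded near-equal fold assignment
#'
#' Shuffles instances with the seed and assigns folds round-robin, so fold
#' sizes differ by at most one (52 instances into 5 folds gives sizes
#' 11, 11, 10, 10, 10).
#'
#' @param n Number of instances.
#' @param n_folds Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in 1..n_folds, one per instance.
#' @export
assign_folds <- function(n, n_folds = 5L, seed = 1L) {
  stopifnot(n >= n_folds)
  perm <- withr::with_seed(seed, sample.int(n))
  folds <- integer(n)
  folds[perm] <- rep(seq_len(n_folds), length.out = n)
  folds
}

#' Nested cross-validated two-period evaluation
#'
#' Runs the full selection + classification protocol on a feature matrix:
#' per fold, [rank_and_select()] on the training folds chooses the features
#' (all features when the selection is empty), the classifier is trained on
#' the training folds and scored on the held-out fold. Results are pooled
#' by [micro_average_accuracy()]; the full-corpus ZeroR baseline accuracy
#' is `max(n1, n2) / (n1 + n2)`; a paired t-test compares per-fold
#' classifier and ZeroR accuracies.
#'
#' @param features data.frame with an `id` column, a `period` column (two
#'   labels) and the feature columns ([feature_names()] by default).
#' @param classifier `"nb"`, `"mlp"` or `"zeror"`.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed driving fold assignment (and MLP training).
#' @param feature_cols Feature column names.
#' @return List of class `evaluation_result`: `classifier`, `fold_accuracy`,
#'   `baseline_fold_accuracy`, `micro_accuracy`, `baseline_accuracy`
#'   (full-corpus majority proportion), `p_value`, `t_test`, `counts`
#'   (pooled per-class correct/incorrect), `fold_counts`, `rankings`
#'   (per-fold `ig_ranking`s), `n_selected` (per-fold selected-set sizes),
#'   `folds`.
#' @export
cross_validate <- function(features, classifier = c("nb", "mlp", "zeror"),
                           n_folds = 5L, seed = 1L,
                           feature_cols = intersect(feature_names(),
                                                    names(features))) {
  classifier <- match.arg(classifier)
  stopifnot(all(c("id", "period") %in% names(features)),
            length(feature_cols) >= 1L)
  y <- as.character(features$period)
  classes <- sort(unique(y))
  if (length(classes) != 2L) stop("exactly two period labels required")
  if (any(table(y) < n_folds))
    stop("each period needs at least ", n_folds, " letters")
  x <- as.data.frame(features[, feature_cols, drop = FALSE])
  n <- nrow(x)
  folds <- assign_folds(n, n_folds, seed)

  fold_counts <- vector("list", n_folds)
  fold_acc <- base_acc <- numeric(n_folds)
  rankings <- vector("list", n_folds)
  n_selected <- integer(n_folds)
  for (f in seq_len(n_folds)) {
    tr <- folds != f; te <- !tr
    rk <- rank_and_select(x[tr, , drop = FALSE], y[tr])
    rankings[[f]] <- rk
    n_selected[f] <- length(rk$selected)
    use <- if (length(rk$selected)) rk$selected else feature_cols
    pred <- switch(classifier,
      nb = fit_predict_nb(x[tr, use, drop = FALSE], y[tr],
                          x[te, use, drop = FALSE]),
      mlp = fit_predict_mlp(x[tr, use, drop = FALSE], y[tr],
                            x[te, use, drop = FALSE],
                            seed = seed * 1000L + f),
      zeror = rep(zeror_baseline(y[tr], y[te])$prediction, sum(te)))
    cc <- confusion_counts(pred, y[te], classes = classes)
    fold_counts[[f]] <- cc$counts
    fold_acc[f] <- cc$accuracy
    base_acc[f] <- zeror_baseline(y[tr], y[te])$accuracy
  }

  pooled <- do.call(rbind, fold_counts)
  pooled <- stats::aggregate(cbind(correct, incorrect) ~ class, pooled, sum)
  tt <- paired_t_test(fold_acc, base_acc)
  structure(list(
    classifier = classifier,
    classes = classes,
    fold_accuracy = fold_acc,
    baseline_fold_accuracy = base_acc,
    micro_accuracy = micro_average_accuracy(fold_counts),
    baseline_accuracy = max(table(y)) / n,
    p_value = tt$p_value,
    t_test = tt,
    counts = pooled,
    fold_counts = fold_counts,
    rankings = rankings,
    n_selected = n_selected,
    folds = folds), class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat("<evaluation_result>", toupper(x$classifier),
      sprintf("micro accuracy %.3f vs baseline %.3f (p = %.3g)\n",
              x$micro_accuracy, x$baseline_accuracy, x$p_value))
  print(x$counts)
  invisible(x)
}
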