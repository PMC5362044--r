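# Within-period stability: split a single period's letters into three
# sequential (chronological) epochs and test each feature for cross-epoch
# differences with a between-subjects one-way ANOVA, flagging significance
# at a Bonferroni-style corrected threshold (default 0.001 for 29 tests).

#' Split one period's letters into three sequential epochs
#'
#' Letters are sorted by date (then id) and divided into chronological
#' thirds; with a remainder r in \{1, 2\}, the extra letters go to the
#' earliest epochs, so sizes differ by at most one (31 letters give
#' 11, 10, 10).
#'
#' @param letters data.frame of letters from a single period (needs `date`,
#'   `id`).
#' @return Integer vector of epoch ids (1 = early, 2 = mid, 3 = late),
#'   aligned with the date-sorted letters; the sorted letters are attached
#'   as attribute `order` (row indices into the input).
#' @export
split_epochs <- function(letters) {
  n <- nrow(letters)
  if (n < 6L) stop("need at least 6 letters to form three epochs")
  ord <- order(letters$date, letters$id)
  base <- n %/% 3L
  r <- n %% 3L
  sizes <- base + as.integer(seq_len(3L) <= r)
  epochs <- rep(1:3, times = sizes)
  out <- integer(n)
  out[ord] <- epochs
  attr(out, "sizes") <- sizes
  out
}

#' One-way ANOVA stability analysis across three epochs
#'
#' For every feature column, fits a between-groups one-way ANOVA of the
#' feature on the epoch factor and reports per-epoch means and standard
#' deviations, the F statistic, the p-value from the F(k-1, n-k)
#' distribution, and significance at the corrected threshold. A feature
#' with zero between- and within-group variance has an undefined F and is
#' reported as not significant with `flag = "degenerate"`.
#'
#' @param features data.frame containing the feature columns.
#' @param epochs Integer epoch assignment (from [split_epochs()]).
#' @param feature_cols Feature columns to test (default: the canonical 29
#'   that are present).
#' @param threshold Significance threshold after multiplicity correction
#'   (default 0.001 for 29 features, the conventional rounding of
#'   0.05 / 29).
#' @return data.frame of class `stability_result`: one row per feature with
#'   `mean_early`, `sd_early`, `mean_mid`, `sd_mid`, `mean_late`,
#'   `sd_late`, `F`, `p_value`, `significant`, `flag`.
#' @export
stability_anova <- function(features, epochs,
                            feature_cols = intersect(feature_names(),
                                                     names(features)),
                            threshold = 0.001) {
  stopifnot(length(epochs) == nrow(features), length(feature_cols) >= 1L)
  if (min(table(epochs)) < 2L) stop("need at least 2 letters per epoch")
  grp <- factor(epochs, levels = 1:3)
  rows <- lapply(feature_cols, function(fc) {
    v <- features[[fc]]
    ms <- tapply(v, grp, mean)
    sds <- tapply(v, grp, stats::sd)
    if (stats::var(v) == 0) {
      return(data.frame(feature = fc, mean_early = ms[1], sd_early = sds[1],
                        mean_mid = ms[2], sd_mid = sds[2],
                        mean_late = ms[3], sd_late = sds[3],
                        F = NA_real_, p_value = NA_real_,
                        significant = FALSE, flag = "degenerate",
                        stringsAsFactors = FALSE))
    }
    fit <- stats::anova(stats::lm(v ~ grp))
    data.frame(feature = fc, mean_early = ms[1], sd_early = sds[1],
               mean_mid = ms[2], sd_mid = sds[2],
               mean_late = ms[3], sd_late = sds[3],
               F = fit$`F value`[1L], p_value = fit$`Pr(>F)`[1L],
               significant = fit$`Pr(>F)`[1L] < threshold,
               flag = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  class(out) <- c("stability_result", "data.frame")
  out
}
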