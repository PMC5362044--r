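# Independent oracles and small fixtures used across tests. These are kept
# deliberately separate from the package implementation: entropy and IG are
# recomputed from contingency tables, ANOVA from sums of squares.

oracle_entropy <- function(y) {
  p <- table(y) / length(y)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# brute-force Information Gain from the bins x labels contingency table
oracle_ig <- function(bins, y) {
  n <- length(y)
  h0 <- oracle_entropy(y)
  hc <- 0
  for (b in unique(bins)) {
    idx <- bins == b
    hc <- hc + sum(idx) / n * oracle_entropy(y[idx])
  }
  h0 - hc
}

# one-way ANOVA F and p from explicit sums of squares
oracle_anova <- function(values, groups) {
  groups <- factor(groups)
  gm <- mean(values)
  k <- nlevels(groups)
  n <- length(values)
  ssb <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(F = f, p = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

# a small tagged letter: tokens + ground-truth coarse tags
toy_tagged_letter <- function(text = paste(
  "the king wrote a long letter to the minister and the king was angry.",
  "the minister replied quickly and the king wrote again."),
  tags = NULL) {
  tl <- tokenize_letter(text, id = "toy")
  if (is.null(tags)) pos_tag(tl) else pos_tag(tl, tags = tags)
}

# feature data.frame wrapper for cross_validate
as_feature_df <- function(x, y) {
  cbind(data.frame(id = sprintf("L%03d", seq_len(nrow(x))), period = y,
                   stringsAsFactors = FALSE),
        as.data.frame(x))
}
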