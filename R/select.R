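# Information-Gain feature ranking with supervised MDL discretization.
#
# Continuous features are discretized per training set with the
# Fayyad-Irani recursive entropy-minimization procedure under the Minimum
# Description Length stopping criterion; Information Gain is then computed
# on the resulting bins, features are ranked in descending IG (ties broken
# by the canonical feature order), and all features with IG strictly
# greater than 0 are selected. A feature for which no cut is accepted falls
# into a single bin and has IG exactly 0, hence is never selected.

.entropy_bits <- function(labels) {
  p <- as.numeric(table(labels)) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Supervised MDL (Fayyad-Irani) discretization cut points
#'
#' Recursively chooses the boundary that minimizes the weighted class-label
#' entropy of the two resulting intervals, accepting a cut only when its
#' information gain exceeds the MDL cost
#' `(log2(N-1) + log2(3^k - 2) - (k H(S) - k1 H(S1) - k2 H(S2))) / N`.
#' A constant feature, or one for which no cut is accepted, yields no cut
#' points (a single bin).
#'
#' @param values Numeric feature values (one per instance).
#' @param labels Class labels (same length).
#' @return Sorted numeric vector of cut points (possibly empty).
#' @export
discretize_mdl <- function(values, labels) {
  stopifnot(length(values) == length(labels), length(values) >= 2L)
  ord <- order(values)
  .mdl_cuts(values[ord], as.character(labels)[ord])
}

.mdl_cuts <- function(v, y) {
  n <- length(v)
  if (n < 2L) return(numeric(0))
  uv <- unique(v)
  if (length(uv) < 2L) return(numeric(0))
  ent_s <- .entropy_bits(y)
  k <- length(unique(y))
  if (k < 2L) return(numeric(0))

  # candidate cuts at midpoints between adjacent distinct values
  best <- NULL
  best_ent <- Inf
  for (i in seq_len(n - 1L)) {
    if (v[i] == v[i + 1L]) next
    e1 <- .entropy_bits(y[1:i])
    e2 <- .entropy_bits(y[(i + 1L):n])
    w <- (i / n) * e1 + ((n - i) / n) * e2
    if (w < best_ent - 1e-12) {
      best_ent <- w
      best <- list(i = i, e1 = e1, e2 = e2,
                   cut = (v[i] + v[i + 1L]) / 2)
    }
  }
  if (is.null(best)) return(numeric(0))

  gain <- ent_s - best_ent
  k1 <- length(unique(y[1:best$i]))
  k2 <- length(unique(y[(best$i + 1L):n]))
  delta <- log2(3^k - 2) - (k * ent_s - k1 * best$e1 - k2 * best$e2)
  threshold <- (log2(n - 1) + delta) / n
  if (gain <= threshold) return(numeric(0))

  left <- 1:best$i
  right <- (best$i + 1L):n
  sort(c(.mdl_cuts(v[left], y[left]), best$cut, .mdl_cuts(v[right], y[right])))
}

#' Assign values to discretization bins
#'
#' @param values Numeric vector.
#' @param cuts Cut points from [discretize_mdl()].
#' @return Integer bin indices (1-based); all 1 when `cuts` is empty.
#' @export
apply_cuts <- function(values, cuts) {
  if (!length(cuts)) return(rep(1L, length(values)))
  findInterval(values, sort(cuts)) + 1L
}

#' Information Gain of a binned feature for the class labels
#'
#' `IG = H(labels) - sum_b (n_b / n) H(labels | bin b)`, in bits.
#'
#' @param bins Bin assignment (any discrete vector).
#' @param labels Class labels (same length).
#' @return IG in bits, >= 0 up to floating error.
#' @export
information_gain <- function(bins, labels) {
  stopifnot(length(bins) == length(labels), length(bins) >= 2L)
  n <- length(labels)
  h <- .entropy_bits(labels)
  cond <- 0
  for (b in unique(bins)) {
    sel <- bins == b
    cond <- cond + (sum(sel) / n) * .entropy_bits(labels[sel])
  }
  max(h - cond, 0)
}

#' Rank all features by Information Gain and select those with IG > 0
#'
#' Per feature: MDL-discretize on the supplied (training) data, compute IG
#' on the bins, then rank in descending IG with ties broken by the
#' canonical column order. An empty selection is a legal outcome.
#'
#' @param x Numeric matrix or data.frame of features (instances x features).
#' @param labels Class labels, one per row.
#' @return List of class `ig_ranking`: `ranking` data.frame
#'   (rank, feature, ig), `selected` character vector of features with
#'   IG > 0, and `ig` named vector in original column order.
#' @export
rank_and_select <- function(x, labels) {
  x <- as.data.frame(x)
  stopifnot(nrow(x) == length(labels))
  ig <- vapply(seq_along(x), function(j) {
    cuts <- discretize_mdl(x[[j]], labels)
    information_gain(apply_cuts(x[[j]], cuts), labels)
  }, numeric(1L))
  names(ig) <- names(x)
  ig[ig < 1e-12] <- 0
  ord <- order(-ig, seq_along(ig))   # ties keep canonical column order
  ranking <- data.frame(rank = seq_along(ig), feature = names(ig)[ord],
                        ig = unname(ig[ord]), stringsAsFactors = FALSE)
  structure(list(ranking = ranking,
                 selected = ranking$feature[ranking$ig > 0],
                 ig = ig),
            class = "ig_ranking")
}

#' @export
print.ig_ranking <- function(x, ...) {
  cat("<ig_ranking>", length(x$selected), "of", nrow(x$ranking),
      "features selected (IG > 0)\n")
  print(utils::head(x$ranking, 10L))
  invisible(x)
}
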