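# Classifiers and evaluation statistics: Gaussian Naive Bayes, a one-hidden
# layer perceptron, the ZeroR majority baseline, micro-average accuracy and
# the paired t-test against the baseline.

#' Gaussian Naive Bayes: fit on training data, predict test labels
#'
#' Class-conditional Gaussian density per feature with class priors equal
#' to training frequencies; prediction is the maximum-posterior class.
#' Per-feature variances are floored at `1e-9` times the overall training
#' variance of that feature (so a within-class-constant feature cannot
#' produce degenerate densities). Posterior ties go to the first class in
#' sorted label order.
#'
#' @param x_train,x_test Numeric matrices/data.frames (instances x features).
#' @param y_train Class labels for the training rows (two or more classes,
#'   each present at least once).
#' @return Character vector of predicted labels for `x_test`.
#' @export
fit_predict_nb <- function(x_train, y_train, x_test) {
  x_train <- as.matrix(x_train); x_test <- as.matrix(x_test)
  y_train <- as.character(y_train)
  classes <- sort(unique(y_train))
  if (length(classes) < 2L) stop("training data must contain every class")
  p <- ncol(x_train)
  overall_var <- apply(x_train, 2L, stats::var)
  overall_var[!is.finite(overall_var) | overall_var <= 0] <- 1
  floor_var <- pmax(1e-9 * overall_var, .Machine$double.xmin)
  mu <- s2 <- matrix(0, length(classes), p)
  prior <- numeric(length(classes))
  for (ci in seq_along(classes)) {
    rows <- y_train == classes[ci]
    prior[ci] <- mean(rows)
    xc <- x_train[rows, , drop = FALSE]
    mu[ci, ] <- colMeans(xc)
    v <- if (nrow(xc) > 1L) apply(xc, 2L, stats::var) else rep(0, p)
    s2[ci, ] <- pmax(v, floor_var)
  }
  log_post <- vapply(seq_along(classes), function(ci) {
    ll <- rep(log(prior[ci]), nrow(x_test))
    for (j in seq_len(p)) {
      ll <- ll + stats::dnorm(x_test[, j], mu[ci, j], sqrt(s2[ci, j]),
                              log = TRUE)
    }
    ll
  }, numeric(nrow(x_test)))
  log_post <- matrix(log_post, nrow = nrow(x_test))
  classes[apply(log_post, 1L, which.max)]   # which.max -> first (sorted) on ties
}

#' Multilayer perceptron: fit on training data, predict test labels
#'
#' Three layers (input, one hidden, output) with sigmoid activations, one
#' output unit per class, squared-error loss, per-instance gradient descent
#' with momentum. Features are standardized to zero mean / unit variance on
#' the training data. Hidden size defaults to `ceiling((p + k) / 2)`.
#' Deterministic given `seed` (weight initialization and epoch shuffling);
#' the global RNG state is left untouched.
#'
#' @param x_train,x_test Numeric matrices/data.frames.
#' @param y_train Training labels.
#' @param seed Integer seed.
#' @param hidden Hidden-layer size; default `ceiling((p + k) / 2)`.
#' @param epochs,rate,momentum Training schedule (defaults 500, 0.3, 0.2).
#' @return Character vector of predicted labels for `x_test`.
#' @export
fit_predict_mlp <- function(x_train, y_train, x_test, seed,
                            hidden = NULL, epochs = 500L, rate = 0.3,
                            momentum = 0.2) {
  x_train <- as.matrix(x_train); x_test <- as.matrix(x_test)
  y_train <- as.character(y_train)
  classes <- sort(unique(y_train))
  if (length(classes) < 2L) stop("training data must contain every class")
  p <- ncol(x_train); k <- length(classes); n <- nrow(x_train)
  if (is.null(hidden)) hidden <- ceiling((p + k) / 2)
  ctr <- colMeans(x_train)
  scl <- apply(x_train, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  xtr <- sweep(sweep(x_train, 2L, ctr), 2L, scl, "/")
  xte <- sweep(sweep(x_test, 2L, ctr), 2L, scl, "/")
  target <- outer(y_train, classes, "==") * 1

  sig <- function(z) 1 / (1 + exp(-z))
  withr::with_seed(seed, {
    w1 <- matrix(stats::runif((p + 1L) * hidden, -0.5, 0.5), p + 1L, hidden)
    w2 <- matrix(stats::runif((hidden + 1L) * k, -0.5, 0.5), hidden + 1L, k)
    d1_prev <- matrix(0, p + 1L, hidden)
    d2_prev <- matrix(0, hidden + 1L, k)
    for (ep in seq_len(epochs)) {
      for (i in sample.int(n)) {
        xi <- c(xtr[i, ], 1)
        h <- sig(drop(xi %*% w1))
        hb <- c(h, 1)
        o <- sig(drop(hb %*% w2))
        err_o <- (target[i, ] - o) * o * (1 - o)
        err_h <- h * (1 - h) * drop(w2[seq_len(hidden), , drop = FALSE] %*% err_o)
        d2 <- rate * outer(hb, err_o) + momentum * d2_prev
        d1 <- rate * outer(xi, err_h) + momentum * d1_prev
        w2 <- w2 + d2; w1 <- w1 + d1
        d2_prev <- d2; d1_prev <- d1
      }
    }
  })
  hb_te <- cbind(sig(cbind(xte, 1) %*% w1), 1)
  o_te <- sig(hb_te %*% w2)
  classes[apply(o_te, 1L, which.max)]
}

#' ZeroR majority-class baseline
#'
#' Predicts the training-majority class for every test instance (ties go to
#' the first class in sorted label order) and returns per-class confusion
#' counts on the test labels.
#'
#' @param y_train Training labels.
#' @param y_test Test labels.
#' @return List: `prediction` (the majority class), `counts` data.frame
#'   with one row per test class (`class`, `correct`, `incorrect`).
#' @export
zeror_baseline <- function(y_train, y_test) {
  y_train <- as.character(y_train); y_test <- as.character(y_test)
  tab <- table(y_train)
  majority <- names(tab)[which.max(tab)]   # ties: first in sorted order
  cc <- confusion_counts(rep(majority, length(y_test)), y_test,
                         classes = sort(unique(c(y_train, y_test))))
  c(list(prediction = majority), cc)
}

#' Per-class confusion counts for one fold
#'
#' @param predicted,actual Label vectors of equal length.
#' @param classes Class universe (defaults to labels seen).
#' @return List with `prediction`-free `counts` data.frame (`class`,
#'   `correct`, `incorrect`) and `accuracy`.
#' @export
confusion_counts <- function(predicted, actual,
                             classes = sort(unique(actual))) {
  stopifnot(length(predicted) == length(actual))
  counts <- do.call(rbind, lapply(classes, function(cl) {
    sel <- actual == cl
    data.frame(class = cl, correct = sum(predicted[sel] == cl),
               incorrect = sum(predicted[sel] != cl),
               stringsAsFactors = FALSE)
  }))
  list(counts = counts,
       accuracy = if (length(actual)) mean(predicted == actual) else NaN)
}

#' Micro-average accuracy over cross-validation folds
#'
#' Pools the per-fold confusion counts: total correctly classified letters
#' (the TP + TN of the two-class problem) over total letters across all
#' folds.
#'
#' @param fold_counts List of per-fold `counts` data.frames (or a single
#'   one) as produced by [confusion_counts()].
#' @return Proportion in \[0, 1\].
#' @export
micro_average_accuracy <- function(fold_counts) {
  if (is.data.frame(fold_counts)) fold_counts <- list(fold_counts)
  correct <- sum(vapply(fold_counts, function(d) sum(d$correct), numeric(1L)))
  total <- sum(vapply(fold_counts, function(d) sum(d$correct) + sum(d$incorrect),
                      numeric(1L)))
  if (total == 0) stop("no instances in confusion counts")
  correct / total
}

#' Paired t-test of per-fold accuracies against the baseline
#'
#' Two-sided paired t-test on the per-fold accuracy differences
#' (df = folds - 1). Degenerate cases are handled explicitly: all-zero
#' differences give p = 1; zero-variance nonzero differences give p = 0
#' with `flag = "zero-variance"`.
#'
#' @param acc_classifier,acc_baseline Equal-length per-fold accuracy
#'   vectors on identical folds.
#' @return List: `t`, `p_value`, `df`, `flag` (`NA` or "zero-variance").
#' @export
paired_t_test <- function(acc_classifier, acc_baseline) {
  stopifnot(length(acc_classifier) == length(acc_baseline),
            length(acc_classifier) >= 2L)
  d <- acc_classifier - acc_baseline
  if (all(d == 0))
    return(list(t = 0, p_value = 1, df = length(d) - 1L, flag = NA_character_))
  if (stats::sd(d) == 0)
    return(list(t = sign(mean(d)) * Inf, p_value = 0,
                df = length(d) - 1L, flag = "zero-variance"))
  ht <- stats::t.test(acc_classifier, acc_baseline, paired = TRUE)
  list(t = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), flag = NA_character_)
}
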