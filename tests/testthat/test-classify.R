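test_that("Gaussian NB classifies well-separated data and breaks ties stably", {
  xtr <- matrix(c(-3, -2.5, -2, 2, 2.5, 3), ncol = 1)
  ytr <- rep(c("healthy", "manic"), each = 3)
  # training point of class healthy comes back as healthy
  expect_equal(fit_predict_nb(xtr, ytr, matrix(-2.5)), "healthy")
  expect_equal(fit_predict_nb(xtr, ytr, matrix(2.5)), "manic")
  # symmetric problem, test at the midpoint: tie goes to the first sorted label
  expect_equal(fit_predict_nb(xtr, ytr, matrix(0)), "healthy")
  expect_error(fit_predict_nb(xtr, rep("manic", 6), matrix(0)), "every class")
})

test_that("NB agrees with an independent reference implementation", {
  skip_if_not_installed("e1071")
  agree <- withr::with_seed(2024, {
    vapply(1:20, function(r) {
      n <- 40L; p <- 5L
      y <- sample(rep(c("m", "h"), each = n / 2))
      shift <- ifelse(y == "m", 0.8, 0)
      x <- matrix(stats::rnorm(n * p) + shift, n, p)
      xte <- matrix(stats::rnorm(20L * p) + rep(c(0.8, 0), each = 10L), 20L, p)
      mine <- fit_predict_nb(x, y, xte)
      ref <- as.character(predict(
        e1071::naiveBayes(as.data.frame(x), factor(y)),
        as.data.frame(xte)))
      mean(mine == ref)
    }, numeric(1))
  })
  expect_gte(mean(agree), 0.98)
})

test_that("the MLP is deterministic, fits separable data, and beats NB on XOR", {
  withr::with_seed(55, {
    n <- 40L
    y <- rep(c("a", "b"), each = n / 2)
    x <- matrix(stats::rnorm(n * 2, ifelse(y == "a", -2, 2)), n, 2)
  })
  p1 <- fit_predict_mlp(x, y, x, seed = 3)
  p2 <- fit_predict_mlp(x, y, x, seed = 3)
  expect_identical(p1, p2)
  expect_equal(mean(p1 == y), 1.0)
  # XOR pattern: non-linear structure NB cannot represent
  withr::with_seed(56, {
    grid <- expand.grid(a = c(0, 1), b = c(0, 1))[rep(1:4, each = 10), ]
    xx <- as.matrix(grid) + matrix(stats::rnorm(80, sd = 0.1), 40, 2)
    yy <- ifelse(grid$a == grid$b, "same", "diff")
  })
  acc_mlp <- mean(fit_predict_mlp(xx, yy, xx, seed = 8) == yy)
  acc_nb <- mean(fit_predict_nb(xx, yy, xx) == yy)
  expect_gt(acc_mlp, 0.9)
  expect_lt(acc_nb, 0.7)
})

test_that("ZeroR reproduces the majority-class accuracies of the reference class sizes", {
  acc <- function(n1, n2) {
    y <- rep(c("p1", "p2"), c(n1, n2))
    zeror_baseline(y, y)$accuracy
  }
  # the six reference two-period class-size pairs
  expect_equal(acc(21, 31), 31 / 52)
  expect_equal(acc(31, 37), 37 / 68)
  expect_equal(acc(31, 47), 47 / 78)
  expect_equal(acc(31, 42), 42 / 73)
  expect_equal(acc(47, 20), 47 / 67)
  expect_equal(acc(47, 11), 47 / 58)
  expect_equal(acc(10, 10), 0.5)  # tie: first sorted class, still half right
  expect_equal(zeror_baseline(rep(c("a", "b"), c(3, 7)), c("a", "b"))$prediction,
               "b")
})

test_that("micro-average accuracy pools fold confusion counts (Eq-style)", {
  f1 <- data.frame(class = c("p1", "p2"), correct = c(11, 28),
                   incorrect = c(10, 3))
  expect_equal(micro_average_accuracy(f1), 39 / 52)
  f2 <- data.frame(class = c("p1", "p2"), correct = c(26, 26),
                   incorrect = c(5, 11))
  expect_equal(micro_average_accuracy(f2), 52 / 68)
  # identity: equals total correct over total instances on random tables
  withr::with_seed(12, {
    for (r in 1:20) {
      tabs <- lapply(1:5, function(f)
        data.frame(class = c("a", "b"), correct = sample(0:10, 2, TRUE),
                   incorrect = sample(0:10, 2, TRUE)))
      tot_c <- sum(vapply(tabs, function(d) sum(d$correct), numeric(1)))
      tot <- tot_c + sum(vapply(tabs, function(d) sum(d$incorrect), numeric(1)))
      if (tot == 0) next
      expect_equal(micro_average_accuracy(tabs), tot_c / tot)
    }
  })
  expect_equal(micro_average_accuracy(
    data.frame(class = "a", correct = 5, incorrect = 0)), 1.0)
})

test_that("paired t-test matches hand computation and degenerate contracts", {
  base <- c(0.6, 0.6, 0.6, 0.6, 0.6)
  # identical vectors
  r0 <- paired_t_test(base, base)
  expect_equal(r0$t, 0)
  expect_equal(r0$p_value, 1)
  # constant nonzero differences: zero-variance flag
  r1 <- paired_t_test(base + 0.1, base)
  expect_equal(r1$p_value, 0)
  expect_equal(r1$flag, "zero-variance")
  # hand-computed example: diffs (0.10, 0.05, 0.15, 0.00, 0.20)
  r2 <- paired_t_test(base + c(0.10, 0.05, 0.15, 0.00, 0.20), base)
  expect_equal(r2$t, 2.828, tolerance = 1e-3)
  expect_equal(r2$p_value, 0.047, tolerance = 1e-2)
  expect_equal(r2$df, 4)
})

test_that("fold assignment is seeded, near-equal and round-robin", {
  f <- assign_folds(52, 5, seed = 1)
  expect_equal(sort(as.vector(table(f)), decreasing = TRUE),
               c(11, 11, 10, 10, 10))
  expect_identical(f, assign_folds(52, 5, seed = 1))
  expect_false(identical(f, assign_folds(52, 5, seed = 2)))
})

test_that("cross-validation is reproducible and beats the baseline on strong effects", {
  withr::with_seed(101, {
    n <- 30L
    y <- rep(c("h", "m"), each = n / 2)
    x <- matrix(stats::rnorm(n * 3, ifelse(y == "m", 1.5, 0)), n, 3,
                dimnames = list(NULL, c("MLC", "W", "D")))
  })
  fd <- as_feature_df(x, y)
  ev1 <- cross_validate(fd, "nb", seed = 4, feature_cols = c("MLC", "W", "D"))
  ev2 <- cross_validate(fd, "nb", seed = 4, feature_cols = c("MLC", "W", "D"))
  expect_identical(ev1$folds, ev2$folds)
  expect_equal(ev1$micro_accuracy, ev2$micro_accuracy)
  expect_gt(ev1$micro_accuracy, ev1$baseline_accuracy)
  # fold test sets partition the corpus
  expect_equal(sort(unique(ev1$folds)), 1:5)
  expect_equal(sum(vapply(ev1$fold_counts,
                          function(d) sum(d$correct) + sum(d$incorrect),
                          numeric(1))), n)
  expect_error(cross_validate(as_feature_df(x[1:8, ], y[c(1:4, 16:19)]), "nb"),
               "at least")
})
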