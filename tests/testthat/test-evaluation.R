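eval_features <- function(n_per = 20, seed = 1, sep = 5) {
  set.seed(seed)
  tasks <- c("A", "B", "C")
  centers <- matrix(c(0, 0, sep, 0, 0, sep), ncol = 2, byrow = TRUE)
  rownames(centers) <- tasks
  y <- rep(tasks, each = n_per)
  X <- t(vapply(y, function(t) centers[t, ] + rnorm(2), numeric(2)))
  colnames(X) <- c("x1", "x2")
  structure(list(temporal = X, spatial = X + 0, combined = cbind(X, X),
                 labels = data.frame(session = 1, block = 1,
                                     interval = seq_along(y), task = y)),
            class = "nirs_features")
}

test_that("repeated stratified CV produces 100 folds and high accuracy on easy data", {
  f <- eval_features()
  cv <- cross_validate(f, c("A", "B"), seed = 1)
  expect_length(cv$fold_accuracies, 100)
  expect_equal(cv$mean_accuracy, mean(cv$fold_accuracies))
  expect_true(all(cv$fold_accuracies >= 0 & cv$fold_accuracies <= 100))
  expect_gt(cv$mean_accuracy, 90)
  # reproducible bit-for-bit under the same seed
  expect_identical(cv, cross_validate(f, c("A", "B"), seed = 1))
  expect_error(cross_validate(f, c("A", "B"), n_folds = 30), "fewer epochs")
})

test_that("stratified folds balance class counts", {
  y <- rep(c("a", "b"), c(40, 20))
  fold <- nirsbci:::stratified_folds(y, 10, seed = 3)
  tab <- table(fold, y)
  expect_true(all(tab[, "a"] == 4))
  expect_true(all(tab[, "b"] == 2))
})

test_that("held-out fold labels and values cannot influence training", {
  f <- eval_features()
  rows <- which(f$labels$task %in% c("A", "B"))
  tr <- rows[1:30]; te <- setdiff(rows, tr)
  g <- f
  g$labels$task[te] <- sample(c("A", "B"), length(te), replace = TRUE)
  g$temporal[te, ] <- 999
  g$spatial[te, ] <- -999
  g$combined[te, ] <- 0
  m1 <- nirsbci:::train_fold(f, tr, c("A", "B"), seed = 5)
  m2 <- nirsbci:::train_fold(g, tr, c("A", "B"), seed = 5)
  expect_identical(m1, m2)
})

test_that("personalization evaluates every subset and finds the planted pair", {
  f <- eval_features(sep = 8)
  p2 <- personalize(f, 2, seed = 2, n_iterations = 1)
  expect_equal(nrow(p2$table), choose(3, 2))
  expect_equal(p2$best_accuracy, max(p2$table$accuracy))
  expect_identical(personalize(f, 2, seed = 2, n_iterations = 1), p2)
  expect_error(personalize(f, 6), "between 2 and 5")
  expect_equal(choose(6, 2:5), c(15, 20, 15, 6))
})

test_that("chance levels and the exact two-class limits match the binomial account", {
  expect_equal(vapply(2:5, function(n) chance_interval(n)$p0, 0),
               100 / (2:5))
  ci2 <- chance_interval(2, 60, 0.05)
  expect_equal(round(ci2$lower, 1), 36.8)
  expect_equal(round(ci2$upper, 1), 63.2)
  # independent oracle: the same limits from the binomial test machinery
  bt <- binom.test(30, 60)$conf.int
  expect_equal(c(ci2$lower, ci2$upper), 100 * as.numeric(bt),
               tolerance = 1e-9)
})

test_that("chance intervals narrow with trials and widen with confidence", {
  a <- chance_interval(4, 60); b <- chance_interval(4, 240)
  expect_true(b$lower > a$lower && b$upper < a$upper)
  c99 <- chance_interval(3, 60, alpha = 0.01)
  c95 <- chance_interval(3, 60, alpha = 0.05)
  expect_true(c99$lower < c95$lower && c99$upper > c95$upper)
  expect_true(exceeds_chance(70, chance_interval(2, 60)))
  expect_false(exceeds_chance(60, chance_interval(2, 60)))
  w <- chance_interval(2, 60, method = "wald")
  expect_lt(abs(w$p0 - 50), 1e-9)
  expect_true(w$lower < 50 && w$upper > 50)
})

test_that("label-shuffled easy data drops to chance", {
  f <- eval_features(sep = 8)
  cv <- cross_validate(f, c("A", "B"), seed = 4, n_iterations = 2,
                       shuffle_labels = TRUE)
  ci <- chance_interval(2, n_trials = 20)
  expect_lt(cv$mean_accuracy, ci$upper)
  expect_gt(cv$mean_accuracy, ci$lower)
})
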