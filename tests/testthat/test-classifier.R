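# Small labelled feature container shared by the classifier tests: three
# feature "sets" derived from one planted 2-D Gaussian problem per task.
toy_features <- function(n_per = 30, tasks = c("A", "B", "C"), sep = 4,
                         seed = 1) {
  set.seed(seed)
  centers <- matrix(c(0, 0, sep, 0, 0, sep), ncol = 2, byrow = TRUE)
  rownames(centers) <- c("A", "B", "C")
  y <- rep(tasks, each = n_per)
  X <- t(vapply(y, function(t) centers[t, ] + rnorm(2), numeric(2)))
  colnames(X) <- c("x1", "x2")
  sp <- cbind(X, x3 = X[, 1] - X[, 2])
  structure(list(temporal = X, spatial = sp,
                 combined = cbind(X, sp2 = sp[, 3]),
                 labels = data.frame(session = 1, block = 1,
                                     interval = seq_along(y), task = y)),
            class = "nirs_features")
}

test_that("LDA separates well-separated classes and matches MASS on them", {
  set.seed(2)
  X <- matrix(c(rnorm(50, -5, 0.5), rnorm(50, 5, 0.5)), ncol = 1,
              dimnames = list(NULL, "v1"))
  y <- rep(c("lo", "hi"), each = 50)
  fit <- lda_train(X, y)
  expect_equal(mean(predict(fit, X) == y), 1)
  # independent cross-check against the reference implementation
  mfit <- MASS::lda(X, grouping = factor(y))
  expect_equal(as.character(predict(mfit, as.data.frame(X))$class),
               as.character(predict(fit, X)))
})

test_that("LDA on identical class distributions performs at chance", {
  set.seed(3)
  X <- matrix(rnorm(200), ncol = 2)
  y <- rep(c("a", "b"), 50)
  fit <- lda_train(X, y)
  Xnew <- matrix(rnorm(4000), ncol = 2)
  acc <- mean(predict(fit, Xnew) == rep(c("a", "b"), 1000))
  expect_gt(acc, 0.4); expect_lt(acc, 0.6)  # within binomial CI of 0.5
})

test_that("duplicating every training point leaves the discriminant unchanged", {
  set.seed(4)
  X <- matrix(rnorm(60), ncol = 2)
  y <- rep(c("a", "b"), 15)
  f1 <- lda_train(X, y)
  f2 <- lda_train(rbind(X, X), c(y, y))
  expect_equal(f1$w, f2$w, tolerance = 1e-9)
  expect_equal(f1$c, f2$c, tolerance = 1e-9)
  expect_error(lda_train(X, rep("a", 30)), "both classes")
})

test_that("bagged ensemble has 10 members, is seeded, and fits separable data", {
  set.seed(5)
  X <- cbind(c(rnorm(20, -3), rnorm(20, 3)),
             c(rnorm(20, 3), rnorm(20, -3)))
  y <- rep(c("a", "b"), each = 20)
  ens <- bagged_lda(X, y, seed = 7)
  expect_length(ens$members, 10)
  for (m in ens$members) expect_length(unique(y[m$idx]), 2)
  expect_identical(predict(ens, X), predict(bagged_lda(X, y, seed = 7), X))
  expect_false(identical(ens$members[[1]]$idx,
                         bagged_lda(X, y, seed = 8)$members[[1]]$idx))
  expect_equal(mean(predict(ens, X) == y), 1)
})

test_that("the three-ensemble majority vote follows the stated rule", {
  expect_equal(binary_vote(c("A", "A", "B"), c("A", "B")), "A")
  expect_equal(binary_vote(c("B", "B", "B"), c("A", "B")), "B")
  # flipping one dissenting vote never changes a 3-0 outcome
  expect_equal(binary_vote(c("B", "B", "A"), c("A", "B")), "B")
  expect_error(binary_vote(c("A", "B"), c("A", "B")), "three")
})

test_that("OVO builds choose(n,2) units and tallies plurality with tie rule", {
  f <- toy_features()
  for (n in 2:3) {
    model <- ovo_fit(f, seq_len(nrow(f$temporal)), c("A", "B", "C")[1:n],
                     seed = 1)
    expect_length(model$units, choose(n, 2))
  }
  expect_equal(choose(2:5, 2), c(1, 3, 6, 10))
  # explicit tallies, including the cyclic three-way tie
  expect_equal(nirsbci:::ovo_tally(c("A", "A", "B"), c("A", "B", "C")), "A")
  expect_equal(nirsbci:::ovo_tally(c("A", "B", "C"), c("A", "B", "C")), "A")
  expect_equal(nirsbci:::ovo_tally(c("B", "B", "C"), c("B", "C", "D")), "B")
})

test_that("OVO prediction is accurate, deterministic, and n=2 reduces to one vote", {
  f <- toy_features(sep = 6)
  rows <- seq_len(nrow(f$temporal))
  model <- ovo_fit(f, rows, c("A", "B", "C"), seed = 3)
  pred <- predict(model, f, rows)
  expect_gt(mean(pred == f$labels$task), 0.95)
  expect_identical(pred, predict(ovo_fit(f, rows, c("A", "B", "C"), seed = 3),
                                 f, rows))
  m2 <- ovo_fit(f, rows[f$labels$task != "C"], c("A", "B"), seed = 3)
  expect_length(m2$units, 1)
  direct <- nirsbci:::predict_binary_unit(m2$units[[1]], f,
                                          rows[f$labels$task != "C"])
  expect_equal(predict(m2, f, rows[f$labels$task != "C"]), direct)
  expect_error(ovo_fit(f, rows, c("A", "Z"), seed = 1), "absent")
})

test_that("consistently relabeling tasks permutes predictions identically", {
  f <- toy_features(seed = 9)
  rows <- seq_len(nrow(f$temporal))
  relab <- c(A = "Q", B = "R", C = "S")
  g <- f
  g$labels$task <- unname(relab[f$labels$task])
  m1 <- ovo_fit(f, rows, c("A", "B", "C"), seed = 2)
  m2 <- ovo_fit(g, rows, c("Q", "R", "S"), seed = 2)
  expect_equal(unname(relab[predict(m1, f, rows)]), predict(m2, g, rows))
})
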