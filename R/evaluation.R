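# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin over folds, keeping per-class counts balanced.
stratified_folds <- function(y, n_folds, seed) {
  fold <- integer(length(y))
  with_stream(seed, "folds", {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

# Train on the non-fold rows, predict the fold rows. Kept separate so tests
# can assert that held-out data never influence selection or weights.
train_fold <- function(features, train_rows, subset, seed, ...) {
  ovo_fit(features, train_rows, subset, seed = seed, ...)
}

#' Repeated stratified cross-validation of a task subset
#'
#' Runs `n_iterations` seeded repetitions of stratified `n_folds`-fold
#' cross-validation of the one-vs-one classifier restricted to the epochs of
#' the given task subset. Within every fold, FCBF feature selection and all
#' ensemble training happen strictly inside the training folds; the held-out
#' fold only ever contributes test predictions. The reported accuracy is the
#' mean over all `n_iterations * n_folds` fold accuracies, in percent.
#'
#' @param features a [epoch_features()] object.
#' @param subset character vector of task labels.
#' @param seed integer seed (folds and bagging both derive from it).
#' @param n_folds,n_iterations cross-validation layout (default 10 x 10).
#' @param shuffle_labels if `TRUE`, class labels of the subset's epochs are
#'   randomly permuted once before cross-validation -- the null calibration
#'   used to check that estimated accuracies sit at chance.
#' @param ... passed to [ovo_fit()].
#' @return object of class `nirs_cv`: `subset`, `mean_accuracy` (%),
#'   `fold_accuracies` (length `n_folds * n_iterations`), `n_epochs`,
#'   `seed`.
#' @export
cross_validate <- function(features, subset, seed = 1, n_folds = 10,
                           n_iterations = 10, shuffle_labels = FALSE, ...) {
  subset <- as.character(subset)
  rows <- which(features$labels$task %in% subset)
  cnt <- table(factor(features$labels$task[rows], levels = subset))
  if (any(cnt < n_folds))
    stop2("class(es) with fewer epochs than folds: ",
          paste(names(cnt)[cnt < n_folds], collapse = ", "))
  feats <- features
  if (shuffle_labels) {
    perm <- with_stream(seed, "shuffle", sample(rows))
    feats$labels$task[rows] <- features$labels$task[perm]
  }
  y <- feats$labels$task[rows]
  acc <- numeric(0)
  for (it in seq_len(n_iterations)) {
    fold <- stratified_folds(y, n_folds, sub_seed(seed, paste0("iter", it)))
    for (f in seq_len(n_folds)) {
      te <- rows[fold == f]
      tr <- rows[fold != f]
      model <- train_fold(feats, tr, subset,
                          seed = sub_seed(seed, paste0("it", it, "f", f)), ...)
      pred <- predict(model, feats, te)
      acc <- c(acc, 100 * mean(pred == feats$labels$task[te]))
    }
  }
  structure(list(subset = subset, mean_accuracy = mean(acc),
                 fold_accuracies = acc, n_epochs = length(rows),
                 seed = seed), class = "nirs_cv")
}

#' @export
print.nirs_cv <- function(x, ...) {
  cat(sprintf("CV accuracy %.1f%% over %d folds (%s; %d epochs)\n",
              x$mean_accuracy, length(x$fold_accuracies),
              paste(x$subset, collapse = "+"), x$n_epochs))
  invisible(x)
}

#' Personalized task-subset selection
#'
#' Evaluates every `choose(6, n)` subset of the available tasks by repeated
#' stratified cross-validation and selects the subset with the highest mean
#' accuracy -- the personalization step that picks each user's best
#' discriminating task combination. Ties go to the lexicographically
#' smallest subset. Results are reproducible bit-for-bit under the same
#' seed.
#'
#' @param features a [epoch_features()] object containing all tasks.
#' @param n number of classes (2-5).
#' @param seed integer seed.
#' @param tasks the task pool (defaults to the sorted unique labels).
#' @param ... passed to [cross_validate()] (e.g. `n_iterations`).
#' @return object of class `nirs_personalization`: `n`, `results` (list of
#'   [cross_validate()] results), `table` (subset/accuracy data frame),
#'   `best_subset`, `best_accuracy`.
#' @export
personalize <- function(features, n, seed = 1, tasks = NULL, ...) {
  if (n < 2 || n > 5) stop2("n must be between 2 and 5")
  tasks <- tasks %||% sort(unique(features$labels$task))
  subsets <- utils::combn(tasks, n, simplify = FALSE)
  results <- lapply(subsets, function(ss)
    cross_validate(features, ss, seed = sub_seed(seed, paste(ss, collapse = "+")),
                   ...))
  key <- vapply(subsets, paste, "", collapse = "+")
  accs <- vapply(results, `[[`, 0, "mean_accuracy")
  best <- order(-accs, key)[1]
  structure(list(
    n = n, results = results,
    table = data.frame(subset = key, accuracy = accs),
    best_subset = subsets[[best]], best_accuracy = accs[best],
    seed = seed
  ), class = "nirs_personalization")
}

#' @export
print.nirs_personalization <- function(x, ...) {
  cat(sprintf("%d-class personalization over %d subsets\n", x$n,
              nrow(x$table)))
  cat(sprintf("best subset: %s (%.1f%%)\n",
              paste(x$best_subset, collapse = "+"), x$best_accuracy))
  invisible(x)
}

#' @export
summary.nirs_personalization <- function(object, ...) {
  tab <- object$table[order(-object$table$accuracy), ]
  rownames(tab) <- NULL
  tab
}

#' @export
plot.nirs_personalization <- function(x, ...) {
  tab <- x$table[order(x$table$accuracy), ]
  graphics::dotchart(tab$accuracy, labels = tab$subset,
                     xlab = "mean CV accuracy (%)",
                     main = sprintf("%d-class task subsets", x$n), ...)
  invisible(x)
}

#' Chance level and its confidence limits
#'
#' The accuracy expected from random classification is `100/n` percent, but
#' with a finite number of trials an observed accuracy fluctuates around it;
#' a classifier only demonstrably beats chance when its accuracy exceeds the
#' upper confidence limit of the chance binomial. Limits are computed around
#' `x = round(p0 * n_trials)` successes in `n_trials` Bernoulli trials,
#' either by the Clopper-Pearson exact interval (default) or the Wald normal
#' approximation.
#'
#' @param n_classes number of classes.
#' @param n_trials trials entering the accuracy estimate (per class under
#'   the default protocol: 60).
#' @param alpha significance level.
#' @param method `"clopper-pearson"` or `"wald"`.
#' @return object of class `nirs_chance`: `p0`, `lower`, `upper` (percent),
#'   `n_trials`, `alpha`, `method`.
#' @examples
#' chance_interval(2, 60)  # (36.8, 63.2) around 50%
#' @export
chance_interval <- function(n_classes, n_trials = 60, alpha = 0.05,
                            method = c("clopper-pearson", "wald")) {
  method <- match.arg(method)
  if (n_trials < 1) stop2("n_trials must be at least 1")
  p0 <- 1 / n_classes
  x <- round(p0 * n_trials)
  if (method == "clopper-pearson") {
    lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n_trials - x + 1)
    upper <- if (x == n_trials) 1 else
      stats::qbeta(1 - alpha / 2, x + 1, n_trials - x)
  } else {
    z <- stats::qnorm(1 - alpha / 2)
    half <- z * sqrt(p0 * (1 - p0) / n_trials)
    lower <- max(0, p0 - half); upper <- min(1, p0 + half)
  }
  structure(list(p0 = 100 * p0, lower = 100 * lower, upper = 100 * upper,
                 n_trials = n_trials, alpha = alpha, method = method),
            class = "nirs_chance")
}

#' @export
print.nirs_chance <- function(x, ...) {
  cat(sprintf("chance %.1f%%, %s %d%% limits (%.1f, %.1f) at %d trials\n",
              x$p0, x$method, round(100 * (1 - x$alpha)), x$lower, x$upper,
              x$n_trials))
  invisible(x)
}

#' Does an accuracy exceed chance?
#'
#' @param accuracy observed accuracy in percent.
#' @param interval a [chance_interval()].
#' @return `TRUE` if the accuracy exceeds the upper confidence limit.
#' @export
exceeds_chance <- function(accuracy, interval) {
  accuracy > interval$upper
}
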