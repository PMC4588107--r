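#' Regularized pooled-covariance linear discriminant
#'
#' Fits Fisher's linear discriminant for a two-class problem with a pooled
#' within-class covariance, lightly ridge-regularized by
#' `gamma * trace(S)/p * I` so that tiny training folds with few selected
#' features cannot make the covariance singular. The decision score is
#' `w'x - c` with `w = S^-1 (mu2 - mu1)` and a threshold incorporating the
#' empirical class priors; positive scores vote for the second class level.
#'
#' @param X numeric matrix (cases x features).
#' @param y two-level class labels.
#' @param gamma ridge fraction.
#' @return object of class `nirs_lda` with `w`, `c`, `levels`.
#' @export
lda_train <- function(X, y, gamma = 1e-6) {
  X <- as.matrix(X)
  y <- factor(y)
  lev <- levels(y)
  if (length(lev) != 2 || any(tabulate(y) == 0))
    stop2("both classes must be present in the training data")
  if (!all(is.finite(X))) stop2("non-finite feature values")
  i1 <- y == lev[1]; i2 <- y == lev[2]
  n1 <- sum(i1); n2 <- sum(i2)
  mu1 <- colMeans(X[i1, , drop = FALSE])
  mu2 <- colMeans(X[i2, , drop = FALSE])
  c1 <- crossprod(sweep(X[i1, , drop = FALSE], 2, mu1))
  c2 <- crossprod(sweep(X[i2, , drop = FALSE], 2, mu2))
  # MLE pooled covariance (divide by n): invariant under duplicating the
  # training set, unlike the unbiased n-2 denominator
  S <- (c1 + c2) / (n1 + n2)
  p <- ncol(X)
  ridge <- gamma * sum(diag(S)) / p
  if (ridge == 0) ridge <- gamma  # fully degenerate data
  S <- S + diag(ridge, p)
  w <- solve(S, mu2 - mu1)
  thr <- sum(w * (mu1 + mu2)) / 2 - log(n2 / n1)
  structure(list(w = w, c = thr, levels = lev), class = "nirs_lda")
}

# Decision scores (positive -> second level).
lda_score <- function(fit, X) {
  as.numeric(as.matrix(X) %*% fit$w) - fit$c
}

#' @export
predict.nirs_lda <- function(object, newdata, ...) {
  factor(object$levels[(lda_score(object, newdata) > 0) + 1],
         levels = object$levels)
}

#' Bagged ensemble of linear discriminants
#'
#' Trains `n_members` linear discriminants on seeded bootstrap resamples
#' (same size as the training set, drawn with replacement; resamples missing
#' a class are redrawn) and predicts by member majority vote, breaking ties
#' by the sign of the summed decision scores.
#'
#' @param X,y training data (two classes).
#' @param n_members ensemble size.
#' @param seed integer seed.
#' @param gamma ridge fraction passed to [lda_train()].
#' @param max_redraws bound on resampling retries per member.
#' @return object of class `nirs_bagged` with the member fits and resample
#'   indices.
#' @export
bagged_lda <- function(X, y, n_members = 10, seed = 1, gamma = 1e-6,
                       max_redraws = 100) {
  X <- as.matrix(X)
  y <- factor(y)
  n <- nrow(X)
  members <- with_stream(seed, "bagging", {
    lapply(seq_len(n_members), function(m) {
      for (try in seq_len(max_redraws)) {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(y[idx])) == 2)
          return(list(fit = lda_train(X[idx, , drop = FALSE], y[idx], gamma),
                      idx = idx))
      }
      stop2("bootstrap resamples kept missing a class")
    })
  })
  structure(list(members = members, levels = levels(y),
                 n_members = n_members), class = "nirs_bagged")
}

#' @export
predict.nirs_bagged <- function(object, newdata, ...) {
  scores <- vapply(object$members,
                   function(m) lda_score(m$fit, newdata),
                   numeric(nrow(as.matrix(newdata))))
  scores <- matrix(scores, ncol = length(object$members))
  votes2 <- rowSums(scores > 0)
  half <- length(object$members) / 2
  pick2 <- votes2 > half | (votes2 == half & rowSums(scores) > 0)
  factor(object$levels[pick2 + 1], levels = object$levels)
}

# One binary OVO unit: per feature set, FCBF selection refit on this unit's
# training data, then a bagged-LDA ensemble on the selected features.
feature_sets <- c("temporal", "spatial", "combined")

train_binary_unit <- function(features, rows, pair, seed, unit_id = 1,
                              n_members = 10, delta = 0, n_bins = 10,
                              gamma = 1e-6) {
  y <- factor(features$labels$task[rows], levels = pair)
  unit <- list(pair = pair)
  for (fs in feature_sets) {
    Xtr <- features[[fs]][rows, , drop = FALSE]
    sel <- fcbf(Xtr, y, delta = delta, n_bins = n_bins)
    # stream keyed by unit position, not label names, so that a consistent
    # relabeling of tasks reproduces the same resamples
    ens <- bagged_lda(Xtr[, sel$selected, drop = FALSE], y,
                      n_members = n_members,
                      seed = sub_seed(seed, paste0(fs, ".unit", unit_id)),
                      gamma = gamma)
    unit[[fs]] <- list(selected = sel$selected, su = sel$su[sel$selected],
                       ensemble = ens)
  }
  unit
}

#' Majority vote of the three feature-set ensembles
#'
#' Combines the three per-feature-set predictions of one binary unit: with
#' three voters over two labels a strict majority always exists.
#'
#' @param votes character vector of three predicted labels.
#' @param pair the two candidate labels.
#' @return the winning label.
#' @export
binary_vote <- function(votes, pair) {
  if (length(votes) != 3) stop2("a binary unit has exactly three ensemble votes")
  if (!all(votes %in% pair)) stop2("vote outside the unit's label pair")
  if (sum(votes == pair[1]) >= 2) pair[1] else pair[2]
}

predict_binary_unit <- function(unit, features, rows) {
  votes <- sapply(feature_sets, function(fs) {
    Xte <- features[[fs]][rows, unit[[fs]]$selected, drop = FALSE]
    as.character(predict(unit[[fs]]$ensemble, Xte))
  })
  votes <- matrix(votes, ncol = 3)
  apply(votes, 1, binary_vote, pair = unit$pair)
}

#' Fit the one-vs-one multi-class voting classifier
#'
#' The full classification model: the n-class problem over the given task
#' subset is decomposed into `choose(n, 2)` binary problems; each binary unit
#' holds three bagged-LDA ensembles (temporal, spatial, combined feature
#' sets), each with its own FCBF feature selection refit on that unit's
#' training rows, and predicts by majority vote of the three ensembles. The
#' multi-class label is the plurality over the binary winners, ties broken by
#' the lowest-indexed task in the subset ordering.
#'
#' @param features a [epoch_features()] object.
#' @param rows training row indices into `features`.
#' @param subset character vector of task labels (>= 2).
#' @param seed integer seed (drives the bagging resamples).
#' @param n_members,delta,n_bins,gamma tuning parameters for the ensembles
#'   and FCBF.
#' @return object of class `nirs_ovo`.
#' @export
ovo_fit <- function(features, rows, subset, seed = 1,
                    n_members = 10, delta = 0, n_bins = 10, gamma = 1e-6) {
  subset <- as.character(subset)
  if (length(subset) < 2) stop2("need at least two tasks")
  present <- unique(features$labels$task[rows])
  if (!all(subset %in% present))
    stop2("task(s) absent from training rows: ",
          paste(setdiff(subset, present), collapse = ", "))
  pairs <- utils::combn(subset, 2, simplify = FALSE)
  units <- lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    r <- rows[features$labels$task[rows] %in% pr]
    train_binary_unit(features, r, pr, seed, unit_id = i,
                      n_members = n_members, delta = delta, n_bins = n_bins,
                      gamma = gamma)
  })
  structure(list(units = units, subset = subset, n_classes = length(subset),
                 seed = seed), class = "nirs_ovo")
}

# Plurality over binary winners; ties -> lowest-indexed task in subset order.
ovo_tally <- function(winners, subset) {
  counts <- vapply(subset, function(t) sum(winners == t), 0L)
  subset[which.max(counts)]
}

#' @export
predict.nirs_ovo <- function(object, features, rows, ...) {
  if (is.null(object$units)) stop2("untrained model")
  wins <- vapply(object$units, predict_binary_unit,
                 character(length(rows)), features = features, rows = rows)
  wins <- matrix(wins, nrow = length(rows))
  apply(wins, 1, ovo_tally, subset = object$subset)
}

#' @export
print.nirs_ovo <- function(x, ...) {
  cat("One-vs-one bagged-LDA classifier:", x$n_classes, "classes (",
      paste(x$subset, collapse = ", "), "),", length(x$units),
      "binary units x 3 feature-set ensembles\n")
  invisible(x)
}
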