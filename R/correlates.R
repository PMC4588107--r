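#' Shapiro-Wilk normality check
#'
#' Thin wrapper around the standard Shapiro-Wilk test, restricted to the
#' small-sample range where it is used here (3 <= n <= 50) to decide between
#' Pearson and Spearman correlation for each characteristic.
#'
#' @param x numeric sample (missing values dropped).
#' @return list with `W` and `p`.
#' @export
shapiro_normality <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3 || length(x) > 50)
    stop2("Shapiro-Wilk supported for 3 <= n <= 50 (got n = ", length(x), ")")
  sw <- stats::shapiro.test(x)
  list(W = unname(sw$statistic), p = sw$p.value)
}

corr_result <- function(variable, method, rho, p, n, alpha) {
  data.frame(variable = variable, method = method, rho = rho, p = p, n = n,
             significant = is.finite(p) & p < alpha)
}

#' Pearson product-moment correlation with two-sided test
#'
#' Pairwise deletion of missing values; errors on zero variance. The p-value
#' is the standard two-sided t-test on the correlation.
#'
#' @param x,y paired numeric samples.
#' @param variable label for the output row.
#' @param alpha significance level for the flag.
#' @return one-row data frame: variable, method, rho, p, n, significant.
#' @export
pearson_corr <- function(x, y, variable = "x", alpha = 0.1) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop2("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop2("zero variance in '", variable, "'")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  corr_result(variable, "Pearson", unname(ct$estimate), ct$p.value,
              length(x), alpha)
}

#' Spearman rank correlation with two-sided test
#'
#' Computed as the Pearson correlation of midranks (ties get average ranks),
#' with the two-sided t-test on the rank correlation.
#'
#' @inheritParams pearson_corr
#' @return one-row data frame as in [pearson_corr()].
#' @export
spearman_corr <- function(x, y, variable = "x", alpha = 0.1) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop2("need at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop2("zero variance in '", variable, "'")
  ct <- stats::cor.test(rx, ry, method = "pearson", alternative = "two.sided")
  corr_result(variable, "Spearman", unname(ct$estimate), ct$p.value,
              length(x), alpha)
}

#' Correlate accuracies with user characteristics
#'
#' Builds the accuracy-vs-characteristics correlation table: continuous
#' characteristics (verbal IQ and the Likert averages) use Pearson
#' correlation when they pass the Shapiro-Wilk normality check (falling back
#' to Spearman otherwise, with a message); dichotomous demographics (gender,
#' handedness) always use Spearman. Missing values are handled by pairwise
#' deletion, so a characteristic missing for one participant simply loses
#' that participant's pair. Age is excluded by default. All-missing or
#' constant characteristics are skipped with a warning.
#'
#' @param accuracies data frame with `participant` and `accuracy` (%).
#' @param profiles data frame as produced by [simulate_participants()] (or
#'   read from CSV): `participant`, `verbal_iq`, Likert columns, `gender`,
#'   `handedness`, optionally `age`.
#' @param alpha significance level (the conventional choice here is 0.1, to
#'   favour sensitivity over specificity at small n).
#' @param include_age include an age row (off by default).
#' @param normality_alpha level for the Shapiro-Wilk gate.
#' @return data frame of class `nirs_correlations`, one row per
#'   characteristic.
#' @export
correlate_report <- function(accuracies, profiles, alpha = 0.1,
                             include_age = FALSE, normality_alpha = 0.05) {
  if (nrow(accuracies) < 4) stop2("need at least 4 participants")
  merged <- merge(accuracies, profiles, by = "participant", sort = TRUE)
  acc <- merged$accuracy
  continuous <- intersect(c("verbal_iq", "tiredness", "concentration",
                            "enjoyment", "ease", "comfort"), names(merged))
  dichotomous <- intersect(c("gender", "handedness"), names(merged))
  if (include_age) dichotomous <- c(dichotomous, intersect("age", names(merged)))
  rows <- list()
  for (v in continuous) {
    x <- merged[[v]]
    if (sum(is.finite(x)) < 3 || stats::sd(x, na.rm = TRUE) == 0) {
      warning("skipping '", v, "': too few values or constant")
      next
    }
    normal <- tryCatch(shapiro_normality(x)$p > normality_alpha,
                       error = function(e) FALSE)
    rows[[v]] <- tryCatch({
      if (normal) pearson_corr(x, acc, v, alpha)
      else {
        message("'", v, "' failed the normality check; using Spearman")
        spearman_corr(x, acc, v, alpha)
      }
    }, error = function(e) {
      warning("skipping '", v, "': ", conditionMessage(e))
      NULL
    })
  }
  for (v in dichotomous) {
    x <- merged[[v]]
    if (!is.numeric(x)) x <- as.integer(factor(x))
    if (sum(is.finite(x)) < 3 || stats::sd(x, na.rm = TRUE) == 0) {
      warning("skipping '", v, "': too few values or constant")
      next
    }
    rows[[v]] <- tryCatch(spearman_corr(x, acc, v, alpha),
                          error = function(e) {
                            warning("skipping '", v, "': ",
                                    conditionMessage(e))
                            NULL
                          })
  }
  if (length(rows) == 0 || all(vapply(rows, is.null, TRUE))) {
    warning("no characteristic could be correlated")
    out <- data.frame(variable = character(), method = character(),
                      rho = numeric(), p = numeric(), n = integer(),
                      significant = logical())
  } else {
    out <- do.call(rbind, rows)
  }
  rownames(out) <- NULL
  structure(out, class = c("nirs_correlations", "data.frame"), alpha = alpha)
}

#' @export
print.nirs_correlations <- function(x, ...) {
  cat("Accuracy-characteristic correlations (alpha =",
      attr(x, "alpha"), ")\n")
  df <- as.data.frame(x)
  df$rho <- round(df$rho, 3); df$p <- round(df$p, 3)
  print(df)
  invisible(x)
}
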