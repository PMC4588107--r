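#' Equal-width discretization fitted on training data
#'
#' FCBF operates on discrete variables; continuous features are binned into
#' `n_bins` equal-width bins over the training minimum/maximum of each
#' feature. The fit must only ever see training data (the cross-validation
#' driver guarantees this); values outside the fitted range are clamped to
#' the end bins.
#'
#' @param X numeric training matrix (epochs x features).
#' @param n_bins number of bins (>= 2).
#' @return object of class `nirs_discretizer`.
#' @export
discretizer_fit <- function(X, n_bins = 10) {
  if (n_bins < 2) stop2("n_bins must be at least 2")
  structure(list(lo = apply(X, 2, min), hi = apply(X, 2, max),
                 n_bins = as.integer(n_bins)), class = "nirs_discretizer")
}

#' @rdname discretizer_fit
#' @param object a fitted discretizer.
#' @export
discretizer_apply <- function(object, X) {
  rng <- object$hi - object$lo
  rng[rng == 0] <- 1
  Xd <- floor(sweep(sweep(X, 2, object$lo), 2, rng, "/") * object$n_bins) + 1L
  Xd[Xd < 1L] <- 1L
  Xd[Xd > object$n_bins] <- object$n_bins
  storage.mode(Xd) <- "integer"
  Xd
}

entropy_counts <- function(counts) {
  p <- counts[counts > 0]
  p <- p / sum(p)
  -sum(p * log2(p))
}

# SU of two integer-coded vectors with known alphabet sizes.
su_int <- function(x, kx, y, ky) {
  n <- length(x)
  hx <- entropy_counts(tabulate(x, kx))
  hy <- entropy_counts(tabulate(y, ky))
  if (hx + hy == 0) return(0)
  hxy <- entropy_counts(tabulate((x - 1L) * ky + y, kx * ky))
  max(0, min(1, 2 * (hx + hy - hxy) / (hx + hy)))
}

#' Symmetrical uncertainty
#'
#' The normalised mutual information `SU(X, Y) = 2 I(X; Y) / (H(X) + H(Y))`
#' with base-2 entropies: 0 for independent variables, 1 for a deterministic
#' one-to-one relation, symmetric in its arguments. Defined as 0 when both
#' variables are constant.
#'
#' @param x,y discrete vectors (factor, integer or character) of equal
#'   length.
#' @return a value in \[0, 1\].
#' @examples
#' symmetrical_uncertainty(c(0, 0, 1, 1), c(0, 1, 0, 1))  # 0
#' @export
symmetrical_uncertainty <- function(x, y) {
  if (length(x) != length(y)) stop2("x and y lengths differ")
  if (length(x) < 2) stop2("need at least two samples")
  xi <- as.integer(factor(x)); yi <- as.integer(factor(y))
  su_int(xi, max(xi), yi, max(yi))
}

#' Fast correlation-based filter (FCBF) feature selection
#'
#' The FCBF algorithm: features are ranked by symmetrical uncertainty (SU)
#' with the class, those with SU above `delta` are kept as candidates, and
#' the ranked list is walked removing every feature j for which an
#' already-kept feature i is more predictive of j than j is of the class
#' (`SU(i, j) >= SU(j, class)`) -- i.e. redundant features are pruned in
#' favour of their dominating predecessors. Ties in the ranking are broken by
#' feature index, making the selection deterministic. If nothing survives
#' (all SU <= delta), the single top-SU feature is returned with a warning.
#'
#' @param X numeric feature matrix (training data only).
#' @param y class labels.
#' @param delta SU relevance threshold.
#' @param n_bins discretization bins (see [discretizer_fit()]).
#' @param Xd optional pre-discretized integer matrix (overrides `X`
#'   discretization).
#' @return object of class `nirs_fcbf`: `selected` (column indices in
#'   decreasing relevance order), `su` (SU with class for all features), and
#'   a `report` data frame (feature, su, kept, removed_by).
#' @export
fcbf <- function(X, y, delta = 0, n_bins = 10, Xd = NULL) {
  if (is.null(Xd)) Xd <- discretizer_apply(discretizer_fit(X, n_bins), X)
  yi <- as.integer(factor(y))
  ky <- max(yi); kb <- max(Xd)
  p <- ncol(Xd)
  su_class <- vapply(seq_len(p), function(j) su_int(Xd[, j], kb, yi, ky), 0)
  cand <- which(su_class > delta)
  fallback <- FALSE
  if (length(cand) == 0) {
    warning("FCBF selected no feature above delta; keeping the top-SU feature")
    cand <- which.max(su_class)
    fallback <- TRUE
  }
  ord <- cand[order(-su_class[cand], cand)]
  removed_by <- integer(p)
  alive <- rep(TRUE, length(ord))
  for (i in seq_along(ord)) {
    if (!alive[i]) next
    xi <- Xd[, ord[i]]
    for (j in seq_along(ord)) {
      if (j <= i || !alive[j]) next
      if (su_int(xi, kb, Xd[, ord[j]], kb) >= su_class[ord[j]]) {
        alive[j] <- FALSE
        removed_by[ord[j]] <- ord[i]
      }
    }
  }
  selected <- ord[alive]
  feat <- colnames(X) %||% paste0("f", seq_len(p))
  structure(list(
    selected = selected, su = su_class, fallback = fallback,
    report = data.frame(feature = feat, su = su_class,
                        kept = seq_len(p) %in% selected,
                        removed_by = ifelse(removed_by > 0,
                                            feat[pmax(removed_by, 1)], ""))
  ), class = "nirs_fcbf")
}
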