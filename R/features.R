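#' Orthonormal discrete Tchebichef polynomials
#'
#' Evaluates the discrete Chebyshev (Tchebichef) polynomials, orthonormalised
#' on the integer grid `x = 0..N-1`, up to `max_order`, via the standard
#' three-term recurrence. Rows are orders 0..max_order, columns grid points;
#' `crossprod(t(P))` is the identity.
#'
#' @param N grid length.
#' @param max_order highest polynomial order (must be < N).
#' @return (max_order+1) x N matrix.
#' @export
tchebichef_polynomials <- function(N, max_order = 4) {
  if (max_order >= N) stop2("polynomial order must be below the grid length")
  x <- 0:(N - 1)
  P <- matrix(0, max_order + 1, N)
  P[1, ] <- 1 / sqrt(N)
  if (max_order >= 1)
    P[2, ] <- (2 * x + 1 - N) * sqrt(3 / (N * (N^2 - 1)))
  if (max_order >= 2) for (p in 2:max_order) {
    c1 <- (2 / p) * sqrt((4 * p^2 - 1) / (N^2 - p^2))
    c2 <- ((1 - N) / p) * sqrt((4 * p^2 - 1) / (N^2 - p^2))
    c3 <- ((p - 1) / p) * sqrt((2 * p + 1) / (2 * p - 3)) *
      sqrt((N^2 - (p - 1)^2) / (N^2 - p^2))
    P[p + 1, ] <- (c1 * x + c2) * P[p, ] - c3 * P[p - 1, ]
  }
  P
}

# (p, q) moment orders with p+q <= max_order, ordered by total order
# ascending then p ascending. 15 pairs for max_order 4.
moment_orders <- function(max_order = 4) {
  idx <- expand.grid(p = 0:max_order, q = 0:max_order)
  idx <- idx[idx$p + idx$q <= max_order, ]
  idx[order(idx$p + idx$q, idx$p), ]
}

#' Tchebichef image moments up to order four
#'
#' Computes the orthonormal discrete Tchebichef moments
#' `eta_pq = sum_r sum_c t_q(r) t_p(c) f(r, c)` of an image on its full
#' rectangular embedding (masked-out pixels contribute zero), for all
#' `p + q <= max_order`; `p` indexes the horizontal (column) polynomial and
#' `q` the vertical (row) polynomial. For the default order 4 this yields 15
#' moments, ordered by total order then `p`.
#'
#' @param image numeric matrix (rows x columns).
#' @param max_order highest total moment order.
#' @return named numeric vector of moments (`m<p><q>`).
#' @examples
#' img <- matrix(1, 21, 61)
#' tchebichef_moments(img)[1]  # only the (0,0) moment is nonzero
#' @export
tchebichef_moments <- function(image, max_order = 4) {
  Pr <- tchebichef_polynomials(nrow(image), max_order)
  Pc <- tchebichef_polynomials(ncol(image), max_order)
  M <- Pr %*% image %*% t(Pc)  # M[q+1, p+1]
  ord <- moment_orders(max_order)
  stats::setNames(M[cbind(ord$q + 1, ord$p + 1)],
                  paste0("m", ord$p, ord$q))
}

#' Topographic interpolation operator
#'
#' Precomputes the linear operator that interpolates the 9 channel values
#' onto the in-mask pixels of the trapezoidal grid, using a cubic
#' radial-basis interpolant (basis `r^3` plus an affine term) centred at the
#' channel pixels. The interpolant passes exactly through the channel values
#' and reproduces constant and planar fields exactly. Because the scheme is
#' linear in the data, interpolation reduces to one precomputed
#' (pixels x channels) matrix product per frame.
#'
#' @param grid an [image_grid()].
#' @param mapping channel pixel coordinates from [map_channels_to_grid()].
#' @return object of class `nirs_interp` holding the evaluation matrix and
#'   pixel bookkeeping.
#' @export
topography_interpolator <- function(grid, mapping) {
  nodes <- cbind(mapping$row, mapping$col)
  if (anyDuplicated(nodes)) stop2("channel pixels must be distinct")
  n <- nrow(nodes)
  D <- as.matrix(stats::dist(nodes))
  K <- D^3
  P <- cbind(1, nodes)
  S <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  pix <- which(grid$mask, arr.ind = TRUE)
  D2 <- sqrt(outer(pix[, 1], nodes[, 1], "-")^2 +
               outer(pix[, 2], nodes[, 2], "-")^2)
  E <- cbind(D2^3, 1, pix)  # npix x (n+3)
  # value at pixels = E %*% solve(S) %*% c(f, 0,0,0): keep first n columns
  W <- t(solve(t(S), t(E)))[, seq_len(n), drop = FALSE]
  structure(list(M = W, pix = pix, grid = grid, mapping = mapping),
            class = "nirs_interp")
}

#' Interpolate a channel frame to a topographic image
#'
#' Renders one frame of per-channel values as the trapezoidal topographic
#' image used for spatial features: in-mask pixels take the cubic
#' radial-basis interpolant of the channel values, outside-mask pixels are
#' zero.
#'
#' @param values numeric vector, one value per channel.
#' @param interp a [topography_interpolator()].
#' @return numeric matrix (grid rows x columns).
#' @export
interpolate_topography <- function(values, interp) {
  if (length(values) != ncol(interp$M))
    stop2("expected ", ncol(interp$M), " channel values")
  if (!all(is.finite(values))) stop2("non-finite channel values")
  img <- matrix(0, interp$grid$n_rows, interp$grid$n_cols)
  img[interp$pix] <- as.numeric(interp$M %*% values)
  img
}

# Linear map from channel values to the 15 moments of the interpolated
# topography: moments of image = T %*% (M %*% f), folded into one matrix.
moment_operator <- function(interp, max_order = 4) {
  grid <- interp$grid
  Pr <- tchebichef_polynomials(grid$n_rows, max_order)
  Pc <- tchebichef_polynomials(grid$n_cols, max_order)
  ord <- moment_orders(max_order)
  Tm <- matrix(0, nrow(ord), nrow(interp$pix))
  for (i in seq_len(nrow(ord)))
    Tm[i, ] <- Pr[ord$q[i] + 1, interp$pix[, 1]] *
      Pc[ord$p[i] + 1, interp$pix[, 2]]
  A <- Tm %*% interp$M
  rownames(A) <- paste0("m", ord$p, ord$q)
  A
}

# Least-squares slope weights over the first k samples, against time
# normalized so the FULL epoch spans [0, 1]: slope(y) = sum(w * y). With this
# convention a ramp rising R over the whole epoch scores R in every window,
# making slopes comparable across window lengths (units: uM per epoch).
slope_weights <- function(k, n_full = k) {
  t <- (seq_len(k) - 1) / (n_full - 1)
  tc <- t - mean(t)
  tc / sum(tc^2)
}

feature_windows <- function(fs, windows_s = c(5, 10, 15, 20)) {
  lapply(windows_s, function(w) max(2L, round(w * fs)))
}

chromophores <- c("HbO", "Hb", "tHb")

#' Temporal features of a trial epoch
#'
#' For each of the four nested time windows (0-5, 0-10, 0-15, 0-20 s), each
#' chromophore and each channel, the least-squares slope of the concentration
#' series against time normalised to \[0, 1\] over that window. Normalising
#' the time axis makes slopes comparable across window lengths (a ramp rising
#' R uM over the full epoch scores R in every window). Ordering is
#' window-major, then chromophore, then channel; 4 x 3 x 9 = 108 features.
#'
#' @param epoch one element of a [segment_trials()] result.
#' @param windows_s window lengths in seconds.
#' @return named numeric vector of length 108 (for 9 channels).
#' @export
temporal_features <- function(epoch, windows_s = c(5, 10, 15, 20)) {
  n_ch <- dim(epoch$conc)[2]
  ks <- feature_windows(epoch$fs, windows_s)
  n_full <- max(unlist(ks))
  out <- numeric(0)
  for (wi in seq_along(ks)) {
    w <- slope_weights(ks[[wi]], n_full)
    for (cm in chromophores) {
      sl <- as.numeric(crossprod(epoch$conc[seq_len(ks[[wi]]), , cm], w))
      names(sl) <- paste0("tmp.w", windows_s[wi], ".", cm, ".ch",
                          seq_len(n_ch))
      out <- c(out, sl)
    }
  }
  out
}

#' Spatial (image-moment) features of a trial epoch
#'
#' At every sample of the epoch, the per-channel values of each chromophore
#' are interpolated onto the trapezoidal grid and summarised by the 15
#' orthonormal Tchebichef moments of order <= 4; the features are the
#' normalised-time slopes of each moment series over the four windows.
#' Ordering is window-major, then chromophore, then moment;
#' 4 x 3 x 15 = 180 features. Because interpolation and moments are both
#' linear, the whole map is one precomputed moments x channels matrix.
#'
#' @param epoch one element of a [segment_trials()] result.
#' @param interp a [topography_interpolator()].
#' @param windows_s window lengths in seconds.
#' @param A optional precomputed [moment_operator()] (else derived from
#'   `interp`).
#' @return named numeric vector of length 180.
#' @export
spatial_features <- function(epoch, interp, windows_s = c(5, 10, 15, 20),
                             A = NULL) {
  if (is.null(A)) A <- moment_operator(interp)
  ks <- feature_windows(epoch$fs, windows_s)
  n_full <- max(unlist(ks))
  out <- numeric(0)
  for (wi in seq_along(ks)) {
    w <- slope_weights(ks[[wi]], n_full)
    for (cm in chromophores) {
      mom <- epoch$conc[seq_len(ks[[wi]]), , cm] %*% t(A)  # samples x 15
      sl <- as.numeric(crossprod(mom, w))
      names(sl) <- paste0("sp.w", windows_s[wi], ".", cm, ".", rownames(A))
      out <- c(out, sl)
    }
  }
  out
}

#' Combine temporal and spatial feature vectors
#'
#' Concatenates the temporal and spatial features of the same epoch
#' (temporal first), giving the 288-feature temporal-spatial set.
#'
#' @param temporal,spatial feature vectors from [temporal_features()] and
#'   [spatial_features()] for the same epoch.
#' @return named numeric vector of length 288.
#' @export
combined_features <- function(temporal, spatial) {
  if (any(names(spatial) %in% names(temporal)))
    stop2("temporal and spatial feature names overlap")
  c(temporal, spatial)
}

#' Feature matrices for a set of epochs
#'
#' Computes the three feature sets of every epoch and stacks them into
#' matrices, together with the epoch labels. This is the input to feature
#' selection, classification and cross-validation.
#'
#' @param epochs a [segment_trials()] result.
#' @param montage a [nirs_montage()].
#' @param grid an [image_grid()].
#' @param windows_s window lengths in seconds.
#' @return object of class `nirs_features`: matrices `temporal` (n x 108),
#'   `spatial` (n x 180), `combined` (n x 288) and `labels` (data frame with
#'   session/block/interval/task).
#' @export
epoch_features <- function(epochs, montage = nirs_montage(),
                           grid = image_grid(),
                           windows_s = c(5, 10, 15, 20)) {
  mapping <- map_channels_to_grid(montage, grid)
  interp <- topography_interpolator(grid, mapping)
  A <- moment_operator(interp)
  tmp <- t(vapply(epochs, temporal_features,
                  temporal_features(epochs[[1]], windows_s),
                  windows_s = windows_s))
  sp <- t(vapply(epochs, spatial_features,
                 spatial_features(epochs[[1]], interp, windows_s, A),
                 interp = interp, windows_s = windows_s, A = A))
  labels <- data.frame(
    session = vapply(epochs, `[[`, 0, "session"),
    block = vapply(epochs, `[[`, 0, "block"),
    interval = vapply(epochs, `[[`, 0, "interval"),
    task = vapply(epochs, `[[`, "", "task")
  )
  structure(list(temporal = tmp, spatial = sp,
                 combined = cbind(tmp, sp), labels = labels),
            class = "nirs_features")
}
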