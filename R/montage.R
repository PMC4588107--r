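#' Source-detector montage
#'
#' Describes the optode layout of the headband: source and detector positions
#' in centimetres on the head surface, the two operating wavelengths, and the
#' source-detector separation that defines a measurement channel. A channel
#' ("point of interrogation") is every source-detector pair whose Euclidean
#' separation equals `pairing_distance` (within `tol`); its position is taken
#' as the midpoint of the pair.
#'
#' The default geometry is a trapezoidal arrangement of 5 sources and 3
#' detectors that yields exactly 9 channels at 3 cm separation, matching the
#' instrument layout the pipeline was designed around. The true optode
#' coordinates of that instrument are not published, so the defaults are a
#' reconstruction honouring the 9-channel / 3 cm constraints; they can be
#' overridden.
#'
#' @param sources numeric matrix (n x 2) of source positions in cm.
#' @param detectors numeric matrix (m x 2) of detector positions in cm.
#' @param wavelengths length-2 numeric, operating wavelengths in nm.
#' @param pairing_distance scalar, source-detector separation (cm) defining a
#'   channel.
#' @param tol tolerance (cm) on the separation match.
#' @return An object of class `nirs_montage` with a `channels` data frame
#'   (`source`, `detector`, `x`, `y`), ordered by source then detector index.
#' @examples
#' m <- nirs_montage()
#' nrow(m$channels)  # 9
#' @export
nirs_montage <- function(sources = default_sources(),
                         detectors = default_detectors(),
                         wavelengths = c(690, 830),
                         pairing_distance = 3.0,
                         tol = 1e-9) {
  sources <- as.matrix(sources)
  detectors <- as.matrix(detectors)
  if (nrow(sources) < 1L || nrow(detectors) < 1L)
    stop2("montage needs at least one source and one detector")
  if (ncol(sources) != 2L || ncol(detectors) != 2L)
    stop2("positions must be 2-D (x, y) in cm")
  if (length(wavelengths) != 2L)
    stop2("exactly two wavelengths are supported")
  m <- structure(list(
    sources = sources, detectors = detectors,
    wavelengths = as.numeric(wavelengths),
    pairing_distance = pairing_distance, tol = tol
  ), class = "nirs_montage")
  m$channels <- derive_channels(m)
  m
}

#' Default optode coordinates of the trapezoidal headband
#'
#' Reconstruction of the 5-source / 3-detector trapezoid (cm): the
#' arrangement in which exactly nine source-detector pairs sit at 3 cm.
#'
#' @return numeric matrix of 2-D positions.
#' @export
default_sources <- function() {
  matrix(c(-6, 1.5, -3, -1.5, 0, 1.5, 3, -1.5, 6, 1.5),
         ncol = 2, byrow = TRUE)
}

#' @rdname default_sources
#' @export
default_detectors <- function() {
  matrix(c(-3, 1.5, 0, -1.5, 3, 1.5), ncol = 2, byrow = TRUE)
}

#' Derive measurement channels from a montage
#'
#' Enumerates every source-detector pair whose separation equals the montage's
#' pairing distance (within tolerance) and returns them in deterministic order
#' (source index, then detector index), with midpoint coordinates.
#'
#' @param montage a [nirs_montage()] object.
#' @return data frame with columns `source`, `detector`, `x`, `y`.
#' @export
derive_channels <- function(montage) {
  src <- montage$sources; det <- montage$detectors
  d <- sqrt(outer(src[, 1], det[, 1], "-")^2 + outer(src[, 2], det[, 2], "-")^2)
  hit <- which(abs(d - montage$pairing_distance) <= montage$tol, arr.ind = TRUE)
  if (nrow(hit) == 0L) {
    stop2("no source-detector pair lies at the pairing distance ",
          montage$pairing_distance, " cm; distance matrix:\n",
          paste(utils::capture.output(print(round(d, 3))), collapse = "\n"))
  }
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
  data.frame(
    source = hit[, 1], detector = hit[, 2],
    x = (src[hit[, 1], 1] + det[hit[, 2], 1]) / 2,
    y = (src[hit[, 1], 2] + det[hit[, 2], 2]) / 2
  )
}

#' @export
print.nirs_montage <- function(x, ...) {
  cat("fNIRS montage:", nrow(x$sources), "sources,", nrow(x$detectors),
      "detectors,", nrow(x$channels), "channels at",
      x$pairing_distance, "cm\n")
  cat("wavelengths:", paste(x$wavelengths, collapse = "/"), "nm\n")
  invisible(x)
}

#' Trapezoidal topographic image grid
#'
#' Pixel raster onto which channel values are interpolated for the spatial
#' feature set: a trapezoid `n_rows` pixels high whose parallel sides are
#' `top_width` (row 1) and `bottom_width` (last row) pixels, with row widths
#' varying linearly between them. Pixels are embedded in an
#' `n_rows x bottom_width` rectangle; the mask flags pixels whose centre lies
#' inside the trapezoid. With the defaults (21 high, sides 21 and 61) the mask
#' holds exactly 0.5*(21+61)*21 = 861 pixels.
#'
#' @param n_rows trapezoid height in pixels.
#' @param top_width,bottom_width widths (pixels) of the parallel sides.
#' @return object of class `nirs_grid`: `mask` (logical matrix), `n_rows`,
#'   `n_cols`, per-row first/last in-mask columns.
#' @examples
#' g <- image_grid()
#' sum(g$mask)  # 861
#' @export
image_grid <- function(n_rows = 21, top_width = 21, bottom_width = 61) {
  if (n_rows < 2 || top_width < 1 || bottom_width < top_width)
    stop2("invalid grid specification")
  widths <- round(top_width + (bottom_width - top_width) *
                    (seq_len(n_rows) - 1) / (n_rows - 1))
  centre <- (bottom_width + 1) / 2
  mask <- matrix(FALSE, n_rows, bottom_width)
  first <- integer(n_rows); last <- integer(n_rows)
  for (r in seq_len(n_rows)) {
    half <- (widths[r] - 1) / 2
    first[r] <- ceiling(centre - half); last[r] <- floor(centre + half)
    mask[r, first[r]:last[r]] <- TRUE
  }
  structure(list(n_rows = n_rows, n_cols = bottom_width, widths = widths,
                 first_col = first, last_col = last, mask = mask),
            class = "nirs_grid")
}

#' Map channel midpoints onto the image grid
#'
#' Places each channel at a pixel of the trapezoidal grid by normalising the
#' channel-midpoint bounding trapezoid onto the pixel trapezoid: the vertical
#' coordinate is mapped affinely between the two parallel sides (the narrower
#' physical side to the narrower pixel side), and the horizontal coordinate is
#' normalised against the bounding trapezoid's linearly interpolated left and
#' right edges at that height. The map is invariant to rigid translation and
#' uniform scaling of the montage.
#'
#' @param montage a [nirs_montage()].
#' @param grid an [image_grid()].
#' @return data frame with one row per channel: `row`, `col` (integer pixel
#'   indices, guaranteed inside the mask).
#' @export
map_channels_to_grid <- function(montage, grid) {
  ch <- montage$channels
  x <- ch$x; y <- ch$y
  ymin <- min(y); ymax <- max(y)
  if (ymax - ymin < 1e-9)
    stop2("degenerate channel layout: all channel midpoints are collinear")
  spread_at <- function(y0) {
    xs <- x[abs(y - y0) < 1e-9]
    if (length(xs) >= 2) range(xs) else range(x)
  }
  rng_min <- spread_at(ymin); rng_max <- spread_at(ymax)
  # narrower physical side maps to row 1 (the short pixel side)
  if (diff(rng_min) <= diff(rng_max)) {
    v <- (y - ymin) / (ymax - ymin); rng_lo <- rng_min; rng_hi <- rng_max
  } else {
    v <- (ymax - y) / (ymax - ymin); rng_lo <- rng_max; rng_hi <- rng_min
  }
  left <- (1 - v) * rng_lo[1] + v * rng_hi[1]
  right <- (1 - v) * rng_lo[2] + v * rng_hi[2]
  if (any(right - left < 1e-9))
    stop2("degenerate channel layout: zero horizontal extent")
  u <- (x - left) / (right - left)
  row <- round(1 + v * (grid$n_rows - 1))
  width_v <- grid$widths[row]
  centre <- (grid$n_cols + 1) / 2
  col <- round(centre + (u - 0.5) * (width_v - 1))
  inside <- grid$mask[cbind(row, col)]
  if (!all(inside))
    stop2("channel(s) ", paste(which(!inside), collapse = ", "),
          " map outside the trapezoid mask")
  data.frame(channel = seq_along(x), row = row, col = col)
}
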