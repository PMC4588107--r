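test_that("feature vectors have the canonical lengths and unique names", {
  ep <- ramp_epoch(1)
  interp <- default_interp()
  tf <- temporal_features(ep)
  sf <- spatial_features(ep, interp)
  cf <- combined_features(tf, sf)
  expect_length(tf, 108)  # 4 windows x 3 chromophores x 9 channels
  expect_length(sf, 180)  # 4 windows x 3 chromophores x 15 moments
  expect_length(cf, 288)
  expect_false(anyDuplicated(names(cf)) > 0)
  expect_equal(names(cf), c(names(tf), names(sf)))
  expect_error(combined_features(tf, tf), "overlap")
})

test_that("temporal slopes: zero on constants, R on a full-epoch ramp", {
  expect_equal(temporal_features(constant_epoch(3.7)), rep(0, 108),
               ignore_attr = TRUE)
  # normalized-time convention: every window of a 20-s ramp rising R scores R
  R <- 2.4
  tf <- temporal_features(ramp_epoch(R))
  expect_equal(tf, rep(R, 108), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("features are offset-invariant and degree-1 homogeneous", {
  hemo <- fixture_hemo()
  ep <- segment_trials(hemo)[[3]]
  interp <- default_interp()
  base <- c(temporal_features(ep), spatial_features(ep, interp))
  shifted <- ep; shifted$conc <- shifted$conc + 5
  expect_equal(c(temporal_features(shifted),
                 spatial_features(shifted, interp)), base,
               tolerance = 1e-9)
  scaled <- ep; scaled$conc <- 3 * scaled$conc
  expect_equal(c(temporal_features(scaled),
                 spatial_features(scaled, interp)), 3 * base,
               tolerance = 1e-9)
})

test_that("topographic interpolation reproduces constants, nodes, and planes", {
  interp <- default_interp()
  img <- interpolate_topography(rep(4.2, 9), interp)
  expect_equal(img[interp$grid$mask], rep(4.2, sum(interp$grid$mask)),
               tolerance = 1e-9)
  set.seed(1)
  v <- rnorm(9)
  img2 <- interpolate_topography(v, interp)
  mp <- interp$mapping
  expect_equal(img2[cbind(mp$row, mp$col)], v, tolerance = 1e-9)
  # planar field sampled at the channels comes back planar everywhere
  plane <- function(r, c) 0.3 * r - 0.7 * c + 2
  imgp <- interpolate_topography(plane(mp$row, mp$col), interp)
  pix <- which(interp$grid$mask, arr.ind = TRUE)
  expect_equal(imgp[pix], plane(pix[, 1], pix[, 2]), tolerance = 1e-6)
  expect_error(interpolate_topography(c(v[-1], NA), interp), "non-finite")
})

test_that("Tchebichef recurrence matches the QR-orthonormalized basis", {
  for (N in c(21, 61)) {
    P <- tchebichef_polynomials(N, 4)
    expect_equal(P %*% t(P), diag(5), tolerance = 1e-9)  # orthonormal
    expect_equal(P, qr_poly_basis(N, 4), tolerance = 1e-9)
  }
})

test_that("moments match a brute-force double sum on random images", {
  set.seed(42)
  img <- matrix(rnorm(21 * 61), 21, 61)
  got <- tchebichef_moments(img)
  Pr <- qr_poly_basis(21, 4); Pc <- qr_poly_basis(61, 4)
  ord <- nirsbci:::moment_orders(4)
  for (i in seq_len(nrow(ord))) {
    acc <- 0
    for (r in 1:21) for (cc in 1:61)
      acc <- acc + Pr[ord$q[i] + 1, r] * Pc[ord$p[i] + 1, cc] * img[r, cc]
    expect_equal(unname(got[i]), acc, tolerance = 1e-9)
  }
  expect_length(got, 15)
})

test_that("constant full-rectangle image has only the zeroth moment", {
  got <- tchebichef_moments(matrix(2, 21, 61))
  expect_equal(unname(got["m00"]), 2 * sqrt(21 * 61), tolerance = 1e-9)
  expect_equal(unname(got[-1]), rep(0, 14), tolerance = 1e-9)
})

test_that("spatially uniform ramps give slopes equal to the unit-mask moments", {
  # all channels following one ramp of rate R makes every frame R*t times the
  # interpolated unit image, so each moment's slope is R times that image's
  # moment (the trapezoid is zero-padded into the rectangle, so left-right
  # symmetry kills odd-p moments but vertical asymmetry keeps some others)
  R <- 1.7
  interp <- default_interp()
  sf <- spatial_features(ramp_epoch(R), interp)
  unit_mom <- tchebichef_moments(interpolate_topography(rep(1, 9), interp))
  for (w in c(5, 10, 15, 20)) for (cm in c("HbO", "Hb", "tHb"))
    expect_equal(unname(sf[paste0("sp.w", w, ".", cm, ".", names(unit_mom))]),
                 unname(R * unit_mom), tolerance = 1e-8)
  expect_lt(max(abs(sf[grepl("\\.m[13][0-9]$", names(sf))])), 1e-8)
  # constant-in-time epochs give all-zero spatial slopes
  expect_equal(spatial_features(constant_epoch(1.5), default_interp()),
               rep(0, 180), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("feature ordering is stable across runs and epochs", {
  hemo <- fixture_hemo()
  eps <- segment_trials(hemo)[1:3]
  f <- epoch_features(eps)
  expect_equal(colnames(f$combined),
               c(colnames(f$temporal), colnames(f$spatial)))
  f2 <- epoch_features(eps)
  expect_identical(f, f2)
  expect_equal(nrow(f$temporal), 3)
  expect_equal(f$labels$task, vapply(eps, `[[`, "", "task"))
})
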