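# Shared fixtures, built once per test run and cached.
.fixture_env <- new.env(parent = emptyenv())

# Feature set for one simulated participant under the default study protocol
# (scaled down via n_sessions where a test does not need the full five).
fixture_features <- function(n_sessions = 1, seed = 42, effects = effect_spec(),
                             noise = noise_spec()) {
  key <- paste0("feat.", n_sessions, ".", seed, ".",
                digest_spec(effects), ".", digest_spec(noise))
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  cfg <- run_config(seed = seed, n_sessions = n_sessions, effects = effects,
                    noise = noise)
  .fixture_env[[key]] <- simulate_participant_features(cfg, 1, 1)
  .fixture_env[[key]]
}

digest_spec <- function(x) {
  v <- unlist(x, use.names = FALSE)
  v <- v[vapply(v, is.numeric, TRUE)]
  round(sum(as.numeric(v) * seq_along(v)), 6)
}

# A small filtered hemodynamic recording (one session, one block).
fixture_hemo <- function(seed = 7) {
  key <- paste0("hemo.", seed)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  sch <- generate_protocol(n_sessions = 1, n_blocks = 1, seed = seed)
  .fixture_env[[key]] <- simulate_hemodynamics(sch, seed = seed)
  .fixture_env[[key]]
}

# A constant-concentration epoch for feature-property tests.
constant_epoch <- function(value = 0, n_ch = 9, fs = 31.25) {
  n <- round(20 * fs)
  list(session = 1, block = 1, interval = 1, task = "MM", onset_s = 30,
       fs = fs,
       conc = array(value, dim = c(n, n_ch, 3),
                    dimnames = list(NULL, paste0("ch", 1:n_ch),
                                    c("HbO", "Hb", "tHb"))))
}

# Epoch whose every channel/chromophore rises linearly by `rise` over 20 s.
ramp_epoch <- function(rise = 1, n_ch = 9, fs = 31.25) {
  ep <- constant_epoch(0, n_ch, fs)
  n <- dim(ep$conc)[1]
  ramp <- seq(0, rise, length.out = n)
  ep$conc <- array(rep(ramp, n_ch * 3), dim = dim(ep$conc),
                   dimnames = dimnames(ep$conc))
  ep
}

default_interp <- function() {
  if (is.null(.fixture_env$interp)) {
    m <- nirs_montage(); g <- image_grid()
    .fixture_env$interp <- topography_interpolator(g, map_channels_to_grid(m, g))
  }
  .fixture_env$interp
}

# Brute-force orthonormal discrete polynomial basis on 0..N-1 via QR of the
# Vandermonde matrix, signs fixed to positive leading coefficients. Used as
# the independent oracle for the recurrence implementation.
qr_poly_basis <- function(N, max_order = 4) {
  V <- outer(0:(N - 1), 0:max_order, "^")
  qr_d <- qr(V)
  Q <- qr.Q(qr_d)
  R <- qr.R(qr_d)
  t(Q %*% diag(sign(diag(R))))
}
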