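#' Low-pass filter specification
#'
#' The pipeline's denoising filter: a third-order Chebyshev type I infinite
#' impulse response low-pass with 0.1 dB passband ripple, passband 0-0.1 Hz
#' and transition band 0.1-0.5 Hz at a 31.25 Hz sampling rate, realized as a
#' cascade of second-order sections. This suppresses the Mayer wave
#' (~0.1 Hz), respiration (0.2-0.4 Hz) and the cardiac pulse (0.5-2 Hz)
#' while keeping the slow task-locked hemodynamic response. Being odd order,
#' the type I design has unit gain at DC.
#'
#' @param order filter order.
#' @param ripple_db passband ripple in dB.
#' @param passband_hz,stopband_hz passband and stopband edges in Hz.
#' @param fs sampling rate in Hz.
#' @param zero_phase if `TRUE`, [filter_recording()] applies the filter
#'   forward-backward (zero phase); the default single causal pass matches a
#'   real-time feedback setting.
#' @return object of class `nirs_filter_spec`.
#' @export
filter_spec <- function(order = 3, ripple_db = 0.1, passband_hz = 0.1,
                        stopband_hz = 0.5, fs = 31.25, zero_phase = FALSE) {
  structure(list(order = order, ripple_db = ripple_db,
                 passband_hz = passband_hz, stopband_hz = stopband_hz,
                 fs = fs, zero_phase = zero_phase),
            class = "nirs_filter_spec")
}

#' Design the Chebyshev low-pass as second-order sections
#'
#' Designs the digital Chebyshev type I low-pass of [filter_spec()] and
#' factors it into a cascade of first/second-order sections by pairing
#' complex-conjugate poles. The design is checked for stability (all poles
#' strictly inside the unit circle) and unit DC gain.
#'
#' @param spec a [filter_spec()].
#' @return object of class `nirs_filter`: `sos` (list of `b`,`a` per
#'   section), the full `b`,`a`, and the spec.
#' @export
design_lowpass <- function(spec = filter_spec()) {
  fl <- signal::cheby1(spec$order, spec$ripple_db,
                       spec$passband_hz / (spec$fs / 2), type = "low")
  b <- as.numeric(fl$b); a <- as.numeric(fl$a)
  poles <- polyroot(rev(a))
  if (any(Mod(poles) >= 1))
    stop2("unstable filter design: pole magnitude(s) ",
          paste(round(Mod(poles)[Mod(poles) >= 1], 6), collapse = ", "))
  zeros <- polyroot(rev(b))
  sos <- pair_sections(zeros, poles)
  # fold the overall gain into the first section so cascade DC gain matches
  g_target <- sum(b) / sum(a)
  g_now <- prod(vapply(sos, function(s) sum(s$b) / sum(s$a), 0))
  sos[[1]]$b <- sos[[1]]$b * g_target / g_now
  h0 <- Mod(freq_response(b, a, 0, spec$fs))
  if (abs(h0 - 1) > 1e-6)
    stop2("DC gain deviates from unity: ", h0)
  structure(list(sos = sos, b = b, a = a, spec = spec),
            class = "nirs_filter")
}

# Pair complex-conjugate roots into real-coefficient biquads; real roots form
# first-order sections (one leftover real root per odd order).
pair_sections <- function(zeros, poles) {
  quads <- function(r) {
    cplx <- r[Im(r) > 1e-9]
    reals <- Re(r[abs(Im(r)) <= 1e-9])
    secs <- lapply(cplx, function(z) c(1, -2 * Re(z), Mod(z)^2))
    while (length(reals) >= 2) {
      secs <- c(secs, list(c(1, -(reals[1] + reals[2]), reals[1] * reals[2])))
      reals <- reals[-(1:2)]
    }
    if (length(reals) == 1) secs <- c(secs, list(c(1, -reals[1])))
    secs
  }
  zs <- quads(zeros); ps <- quads(poles)
  n <- max(length(zs), length(ps))
  lapply(seq_len(n), function(i) {
    list(b = if (i <= length(zs)) zs[[i]] else 1,
         a = if (i <= length(ps)) ps[[i]] else 1)
  })
}

# Complex frequency response of b/a at frequencies f (Hz).
freq_response <- function(b, a, f, fs) {
  vapply(f, function(f1) {
    z <- exp(-1i * 2 * pi * f1 / fs * (seq_along(b) - 1))
    num <- sum(b * z)
    z <- exp(-1i * 2 * pi * f1 / fs * (seq_along(a) - 1))
    num / sum(a * z)
  }, complex(1))
}

#' Filter magnitude response
#'
#' @param filt a [design_lowpass()] filter.
#' @param f frequencies in Hz.
#' @return magnitude response (linear scale) at `f`.
#' @export
filter_gain <- function(filt, f) {
  Mod(freq_response(filt$b, filt$a, f, filt$spec$fs))
}

apply_cascade <- function(filt, x) {
  for (s in filt$sos) x <- as.numeric(signal::filter(s$b, s$a, x))
  x
}

#' Filter a hemodynamic recording
#'
#' Applies the low-pass to every channel's HbO and Hb series of every block
#' (causal single pass by default; forward-backward if the spec sets
#' `zero_phase`). Total hemoglobin is re-derived as the sum after filtering,
#' which for a linear filter equals filtering the sum.
#'
#' @param hemo a `nirs_hemo_set`.
#' @param filt a [design_lowpass()] filter (designed at the recording's
#'   sampling rate).
#' @return a filtered `nirs_hemo_set`.
#' @export
filter_recording <- function(hemo, filt = design_lowpass()) {
  blocks <- lapply(hemo, function(bl) {
    if (abs(bl$fs - filt$spec$fs) > 1e-9)
      stop2("recording sampled at ", bl$fs, " Hz but filter designed for ",
            filt$spec$fs, " Hz")
    run <- if (filt$spec$zero_phase)
      function(x) as.numeric(signal::filtfilt(filt$b, filt$a, x))
    else function(x) apply_cascade(filt, x)
    for (ch in seq_len(dim(bl$conc)[2])) {
      hbo <- run(bl$conc[, ch, "HbO"])
      hb <- run(bl$conc[, ch, "Hb"])
      bl$conc[, ch, "HbO"] <- hbo
      bl$conc[, ch, "Hb"] <- hb
      bl$conc[, ch, "tHb"] <- hbo + hb
    }
    bl
  })
  structure(blocks, class = "nirs_hemo_set", fs = attr(hemo, "fs"))
}

#' Segment task trials from a recording
#'
#' Cuts one epoch per task interval: the half-open 20-s window starting at
#' task onset, `round(20 * fs)` samples long (625 at 31.25 Hz). Each epoch is
#' referenced by subtracting its first sample per channel/chromophore, fixing
#' the topography baseline (slope features are offset-invariant regardless).
#' Trials listed in `exclusions` (e.g. motion artifacts) are dropped.
#'
#' @param hemo a `nirs_hemo_set` whose blocks carry their `events`.
#' @param task_s epoch duration in seconds.
#' @param exclusions optional data frame (`session`, `block`,
#'   `interval`) of trials to discard; `interval` indexes the task intervals
#'   of the block in onset order.
#' @param reference subtract the epoch's first sample (default TRUE).
#' @return list of class `nirs_epochs`; each element has `session`, `block`,
#'   `interval`, `task`, `onset_s`, `fs` and `conc`
#'   (samples x channels x chromophore).
#' @export
segment_trials <- function(hemo, task_s = 20, exclusions = NULL,
                           reference = TRUE) {
  epochs <- list()
  for (bl in hemo) {
    ev <- bl$events[order(bl$events$onset_s), , drop = FALSE]
    n <- dim(bl$conc)[1]
    len <- round(task_s * bl$fs)
    i0 <- floor(ev$onset_s * bl$fs) + 1
    bad <- which(i0 + len - 1 > n)
    if (length(bad))
      stop2("task onset(s) past end of recording (session ", bl$session,
            ", block ", bl$block, "): intervals ",
            paste(bad, collapse = ", "))
    for (k in seq_len(nrow(ev))) {
      if (!is.null(exclusions) &&
          any(exclusions$session == bl$session &
                exclusions$block == bl$block &
                exclusions$interval == k)) next
      win <- bl$conc[i0[k]:(i0[k] + len - 1), , , drop = FALSE]
      if (reference)
        win <- sweep(win, c(2, 3), win[1, , ], "-")
      epochs[[length(epochs) + 1]] <-
        list(session = bl$session, block = bl$block, interval = k,
             task = ev$task[k], onset_s = ev$onset_s[k], fs = bl$fs,
             conc = win)
    }
  }
  structure(epochs, class = "nirs_epochs")
}
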