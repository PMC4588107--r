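#' Task effect specification for the hemodynamic simulator
#'
#' Defines the ground-truth activation pattern the generator plants: a
#' per-task, per-channel oxygenated-hemoglobin (HbO) response amplitude in
#' micromolar, a fixed Hb/HbO amplitude ratio (deoxygenated hemoglobin
#' typically moves opposite to HbO at about a third of the magnitude), the
#' canonical double-gamma hemodynamic response shape, and lognormal
#' trial-to-trial amplitude jitter. Total hemoglobin is always exactly
#' HbO + Hb.
#'
#' The default amplitude map assigns each of the six mental tasks a distinct
#' topographic pattern over the 9 channels, scaled so that some task pairs
#' (notably mental math vs unconstrained rest) are far more separable than
#' others (e.g. mental math vs word generation) -- the structure that makes
#' task-subset personalization meaningful.
#'
#' @param amplitudes numeric task x channel matrix of HbO amplitudes (uM);
#'   rownames are task labels.
#' @param hb_ratio Hb amplitude as a fraction of HbO amplitude.
#' @param hrf_peak_s,hrf_undershoot_s,hrf_ratio double-gamma HRF parameters:
#'   response peak time, undershoot peak time, undershoot/peak ratio.
#' @param jitter lognormal sd of the per-trial amplitude multiplier.
#' @param amplitude_scale global multiplier on the amplitude map.
#' @return object of class `nirs_effects`.
#' @export
effect_spec <- function(amplitudes = default_amplitudes(),
                        hb_ratio = -1 / 3,
                        hrf_peak_s = 6, hrf_undershoot_s = 16,
                        hrf_ratio = 1 / 6,
                        jitter = 0.2, amplitude_scale = 1) {
  amplitudes <- as.matrix(amplitudes)
  if (!all(is.finite(amplitudes))) stop2("effect amplitudes must be finite")
  if (is.null(rownames(amplitudes))) stop2("amplitude rows must be named by task")
  structure(list(amplitudes = amplitudes * amplitude_scale,
                 hb_ratio = hb_ratio, hrf_peak_s = hrf_peak_s,
                 hrf_undershoot_s = hrf_undershoot_s, hrf_ratio = hrf_ratio,
                 jitter = jitter), class = "nirs_effects")
}

#' Default task-by-channel HbO amplitude map (uM)
#'
#' Each of the six mental tasks gets a distinct topographic activation
#' pattern over the nine channels; mental math (MM) vs unconstrained rest
#' (RR) is the most separable pair by pairwise contrast, mental math vs word
#' generation (WG) the least.
#'
#' @return 6 x 9 numeric matrix with task rownames.
#' @export
default_amplitudes <- function() {
  a <- rbind(
    MM = c(1.0, 1.0, 0.9, 0.7, 0.5, 0.3, 0.2, 0.1, 0.1),
    WG = c(0.8, 0.9, 0.8, 0.6, 0.5, 0.3, 0.2, 0.2, 0.1),
    HT = c(0.2, 0.3, 0.3, 0.5, 0.7, 0.8, 0.6, 0.5, 0.4),
    RF = c(0.1, 0.1, 0.2, 0.3, 0.4, 0.5, 0.7, 0.8, 0.7),
    RS = c(0.3, 0.2, 0.3, 0.2, 0.3, 0.2, 0.3, 0.2, 0.3),
    RR = c(-0.1, -0.1, -0.1, -0.1, -0.1, -0.1, -0.1, -0.1, -0.1)
  )
  colnames(a) <- paste0("ch", 1:9)
  a
}

#' Physiological and measurement noise specification
#'
#' Amplitudes (uM, standard deviation for stochastic components) of the noise
#' processes superimposed on the simulated concentration series: the Mayer
#' wave (arterial-pressure oscillation near 0.1 Hz), respiration (0.2-0.4 Hz
#' band), the cardiac pulse, 1/f baseline drift, and white noise; plus the
#' relative sd of multiplicative measurement noise applied to raw optical
#' intensities. Hb noise components are scaled by `hb_noise_ratio`. `scale`
#' multiplies every amplitude (0 disables all noise).
#'
#' @param mayer_hz,mayer_uM Mayer wave centre frequency and amplitude.
#' @param mayer_phase_jitter sd (rad/sqrt(s)) of the Mayer phase random walk.
#' @param resp_band_hz,resp_uM respiration frequency band (a rate is drawn
#'   uniformly per block) and amplitude.
#' @param cardiac_hz,cardiac_uM cardiac rate and amplitude.
#' @param drift_exponent,drift_uM 1/f^a drift exponent and sd.
#' @param white_uM white noise sd.
#' @param intensity_rel_sd relative sd of intensity measurement noise.
#' @param hb_noise_ratio Hb noise amplitude as a fraction of HbO noise.
#' @param scale global noise multiplier.
#' @return object of class `nirs_noise`.
#' @export
noise_spec <- function(mayer_hz = 0.1, mayer_uM = 0.3,
                       mayer_phase_jitter = 0.1,
                       resp_band_hz = c(0.2, 0.4), resp_uM = 0.2,
                       cardiac_hz = 1.1, cardiac_uM = 0.2,
                       drift_exponent = 1, drift_uM = 0.3,
                       white_uM = 0.1, intensity_rel_sd = 1e-3,
                       hb_noise_ratio = 1 / 3, scale = 1) {
  structure(list(mayer_hz = mayer_hz, mayer_uM = mayer_uM * scale,
                 mayer_phase_jitter = mayer_phase_jitter,
                 resp_band_hz = resp_band_hz, resp_uM = resp_uM * scale,
                 cardiac_hz = cardiac_hz, cardiac_uM = cardiac_uM * scale,
                 drift_exponent = drift_exponent, drift_uM = drift_uM * scale,
                 white_uM = white_uM * scale,
                 intensity_rel_sd = intensity_rel_sd * scale,
                 hb_noise_ratio = hb_noise_ratio), class = "nirs_noise")
}

# Double-gamma HRF convolved with a task_s boxcar, sampled at fs, peak
# normalized to 1. Returned kernel covers task_s + 32 s.
hrf_boxcar_kernel <- function(effects, fs, task_s = 20) {
  dt <- 1 / fs
  t_h <- seq(0, 32, by = dt)
  a1 <- effects$hrf_peak_s; a2 <- effects$hrf_undershoot_s
  h <- stats::dgamma(t_h, shape = a1, rate = 1) -
    effects$hrf_ratio * stats::dgamma(t_h, shape = a2, rate = 1)
  box <- rep(1, round(task_s * fs))
  k <- stats::convolve(c(h, numeric(length(box))),
                       rev(c(box, numeric(length(h)))), type = "open")
  k <- k[seq_len(length(h) + length(box))] * dt
  k / max(k)
}

# FFT synthesis of 1/f^a noise with unit sd.
one_over_f <- function(n, exponent) {
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)  # symmetric frequency index
  spec <- f^(-exponent / 2)
  spec[1] <- 0
  z <- stats::rnorm(n) + 1i * stats::rnorm(n)
  x <- Re(stats::fft(z * spec, inverse = TRUE))
  s <- stats::sd(x)
  if (s == 0) numeric(n) else x / s
}

noise_series <- function(n, fs, noise, seed, tag) {
  t <- (seq_len(n) - 1) / fs
  out <- numeric(n)
  if (noise$mayer_uM > 0) out <- out + with_stream(seed, paste0("mayer.", tag), {
    phi0 <- stats::runif(1, 0, 2 * pi)
    jit <- cumsum(stats::rnorm(n, 0, noise$mayer_phase_jitter / sqrt(fs)))
    noise$mayer_uM * sin(2 * pi * noise$mayer_hz * t + phi0 + jit)
  })
  if (noise$resp_uM > 0) out <- out + with_stream(seed, paste0("resp.", tag), {
    fr <- stats::runif(1, noise$resp_band_hz[1], noise$resp_band_hz[2])
    noise$resp_uM * sin(2 * pi * fr * t + stats::runif(1, 0, 2 * pi))
  })
  if (noise$cardiac_uM > 0) out <- out + with_stream(seed, paste0("card.", tag), {
    noise$cardiac_uM * sin(2 * pi * noise$cardiac_hz * t +
                             stats::runif(1, 0, 2 * pi))
  })
  if (noise$drift_uM > 0) out <- out + with_stream(seed, paste0("drift.", tag), {
    noise$drift_uM * one_over_f(n, noise$drift_exponent)
  })
  if (noise$white_uM > 0) out <- out + with_stream(seed, paste0("white.", tag), {
    stats::rnorm(n, 0, noise$white_uM)
  })
  out
}

#' Simulate task-dependent hemodynamic concentration series
#'
#' Forward model for the study protocol: for every block of the schedule,
#' each channel's HbO series is the sum over task intervals of the planted
#' amplitude times a jittered double-gamma HRF convolved with the 20-s task
#' boxcar, plus additive physiological noise (Mayer wave, respiration,
#' cardiac, 1/f drift, white). Hb is generated analogously with the
#' `hb_ratio` amplitude scaling and independent noise draws; total hemoglobin
#' is HbO + Hb exactly at every sample. Deterministic given `seed`.
#'
#' @param schedule a [generate_protocol()] schedule.
#' @param effects an [effect_spec()].
#' @param noise a [noise_spec()].
#' @param montage a [nirs_montage()] (defines the channel count).
#' @param fs sampling rate, Hz; must exceed twice the cardiac rate.
#' @param seed integer seed.
#' @return object of class `nirs_hemo_set`: a list of per-block recordings,
#'   each with `session`, `block`, `fs`, `conc` (samples x channels x
#'   chromophore array, chromophores HbO/Hb/tHb, uM) and `events` (the task
#'   intervals of that block).
#' @export
simulate_hemodynamics <- function(schedule, effects = effect_spec(),
                                  noise = noise_spec(),
                                  montage = nirs_montage(),
                                  fs = 31.25, seed = 1) {
  if (noise$cardiac_uM > 0 && fs <= 2 * noise$cardiac_hz)
    stop2("sampling rate must exceed twice the cardiac rate")
  n_ch <- nrow(montage$channels)
  tasks <- rownames(effects$amplitudes)
  kern <- hrf_boxcar_kernel(effects, fs, task_s = attr(schedule, "task_s") %||% 20)
  dur <- block_duration(schedule)
  n <- ceiling(dur * fs)
  keys <- unique(schedule[, c("session", "block")])
  blocks <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    s <- keys$session[i]; b <- keys$block[i]
    rows <- schedule[schedule$session == s & schedule$block == b &
                       schedule$phase == "task", ]
    tag <- paste0("s", s, "b", b)
    clean <- matrix(0, n, n_ch)
    jit <- with_stream(seed, paste0("jitter.", tag), {
      if (effects$jitter > 0) exp(stats::rnorm(nrow(rows), 0, effects$jitter))
      else rep(1, nrow(rows))
    })
    for (k in seq_len(nrow(rows))) {
      task <- rows$task[k]
      if (!task %in% tasks)
        stop2("schedule task '", task, "' missing from effect amplitudes")
      i0 <- floor(rows$onset_s[k] * fs) + 1
      idx <- i0:min(n, i0 + length(kern) - 1)
      amp <- effects$amplitudes[task, ] * jit[k]
      clean[idx, ] <- clean[idx, ] + outer(kern[seq_along(idx)], amp)
    }
    conc <- array(0, dim = c(n, n_ch, 3),
                  dimnames = list(NULL, paste0("ch", seq_len(n_ch)),
                                  c("HbO", "Hb", "tHb")))
    for (ch in seq_len(n_ch)) {
      hbo <- clean[, ch] +
        noise_series(n, fs, noise, seed, paste0(tag, ".hbo.ch", ch))
      hbn <- noise  # Hb noise: same processes, scaled amplitudes
      for (f in c("mayer_uM", "resp_uM", "cardiac_uM", "drift_uM", "white_uM"))
        hbn[[f]] <- noise[[f]] * abs(noise$hb_noise_ratio)
      hb <- clean[, ch] * effects$hb_ratio +
        noise_series(n, fs, hbn, seed, paste0(tag, ".hb.ch", ch))
      conc[, ch, "HbO"] <- hbo
      conc[, ch, "Hb"] <- hb
      conc[, ch, "tHb"] <- hbo + hb
    }
    blocks[[i]] <- list(session = s, block = b, fs = fs, conc = conc,
                        events = rows[, c("onset_s", "duration_s", "task")])
  }
  structure(blocks, class = "nirs_hemo_set", fs = fs)
}

#' Forward-model concentrations to raw optical intensities
#'
#' Inverts the modified Beer-Lambert law: for each wavelength,
#' `I(t) = I0 * 10^-(eps_HbO dHbO + eps_Hb dHb) d DPF * (1 + measurement
#' noise)`, with concentrations in mM inside the exponent. The exact inverse
#' of [mbll()] when noise is disabled.
#'
#' @param hemo a `nirs_hemo_set` from [simulate_hemodynamics()].
#' @param optics an [optics_parameters()].
#' @param noise a [noise_spec()] (only `intensity_rel_sd` is used).
#' @param seed integer seed for the measurement noise.
#' @return object of class `nirs_raw_set`: per-block list with `intensity`
#'   (samples x channels x wavelength array), `fs`, `wavelengths`, `events`.
#' @export
hemodynamics_to_intensity <- function(hemo, optics = optics_parameters(),
                                      noise = noise_spec(), seed = 1) {
  if (any(optics$I0 <= 0)) stop2("reference intensity I0 must be positive")
  blocks <- lapply(hemo, function(bl) {
    n <- dim(bl$conc)[1]; n_ch <- dim(bl$conc)[2]
    inten <- array(0, dim = c(n, n_ch, 2),
                   dimnames = list(NULL, dimnames(bl$conc)[[2]],
                                   paste0("wl", optics$wavelengths)))
    for (w in 1:2) {
      od <- (optics$extinction[w, "HbO"] * bl$conc[, , "HbO"] +
               optics$extinction[w, "Hb"] * bl$conc[, , "Hb"]) / 1000 *
        optics$distance_cm * optics$dpf[w]
      inten[, , w] <- optics$I0 * 10^(-od)
    }
    if (noise$intensity_rel_sd > 0) {
      tag <- paste0("imeas.s", bl$session, "b", bl$block)
      inten <- inten * (1 + with_stream(seed, tag, {
        array(stats::rnorm(length(inten), 0, noise$intensity_rel_sd),
              dim = dim(inten))
      }))
    }
    list(session = bl$session, block = bl$block, fs = bl$fs,
         wavelengths = optics$wavelengths, intensity = inten,
         events = bl$events)
  })
  structure(blocks, class = "nirs_raw_set", fs = attr(hemo, "fs"))
}

#' Participant cohort specification
#'
#' Distributions for the simulated participant characteristics: verbal IQ
#' (normal), the five 7-point Likert post-session averages (truncated normal
#' on \[1, 7\]: tiredness, concentration, enjoyment, ease of session, headgear
#' comfort), gender and handedness (Bernoulli). `iq_coupling` links verbal IQ
#' to each participant's effect amplitude scale via
#' `scale = exp(coupling * (IQ - iq_mean) / iq_sd)`, a monotone link; the
#' default negative coupling emulates stronger hemodynamic responses in
#' participants with lower verbal IQ.
#'
#' @param n_participants cohort size.
#' @param iq_mean,iq_sd verbal IQ distribution.
#' @param likert_mean,likert_sd named length-5 vectors for the Likert items.
#' @param p_female,p_right Bernoulli probabilities for gender/handedness.
#' @param iq_coupling coupling coefficient (0 = none).
#' @param n_missing_iq number of participants with missing IQ (the test is
#'   optional in practice).
#' @return object of class `nirs_participant_spec`.
#' @export
participant_spec <- function(n_participants = 10, iq_mean = 100, iq_sd = 12,
                             likert_mean = c(tiredness = 3.5,
                                             concentration = 5,
                                             enjoyment = 5,
                                             ease = 4.5, comfort = 5.3),
                             likert_sd = c(tiredness = 1.2,
                                           concentration = 1,
                                           enjoyment = 1,
                                           ease = 1.2, comfort = 0.9),
                             p_female = 0.6, p_right = 0.8,
                             iq_coupling = -0.5, n_missing_iq = 1) {
  structure(list(n_participants = n_participants, iq_mean = iq_mean,
                 iq_sd = iq_sd, likert_mean = likert_mean,
                 likert_sd = likert_sd, p_female = p_female,
                 p_right = p_right, iq_coupling = iq_coupling,
                 n_missing_iq = min(n_missing_iq, n_participants)),
            class = "nirs_participant_spec")
}

#' Simulate participant profiles and per-participant effect scales
#'
#' Draws a cohort of participant characteristic profiles and, for each
#' participant, the effect amplitude scale implied by the IQ coupling.
#' Likert averages are truncated to \[1, 7\]. Missing IQ (if requested) is
#' assigned to the last participant(s); the coupling is computed from the
#' true (pre-missingness) IQ so the planted relation is well defined.
#'
#' @param spec a [participant_spec()].
#' @param seed integer seed.
#' @return list with `profiles` (data frame: participant, verbal_iq, the five
#'   Likert averages, gender, handedness) and `effect_scale` (numeric vector).
#' @export
simulate_participants <- function(spec = participant_spec(), seed = 1) {
  n <- spec$n_participants
  with_stream(seed, "participants", {
    iq <- stats::rnorm(n, spec$iq_mean, spec$iq_sd)
    lik <- sapply(names(spec$likert_mean), function(v) {
      pmin(7, pmax(1, stats::rnorm(n, spec$likert_mean[[v]],
                                   spec$likert_sd[[v]])))
    })
    gender <- ifelse(stats::runif(n) < spec$p_female, "F", "M")
    hand <- ifelse(stats::runif(n) < spec$p_right, "R", "L")
    scale <- exp(spec$iq_coupling * (iq - spec$iq_mean) / spec$iq_sd)
    iq_obs <- iq
    if (spec$n_missing_iq > 0)
      iq_obs[seq(n, by = -1, length.out = spec$n_missing_iq)] <- NA
    profiles <- data.frame(participant = seq_len(n),
                           verbal_iq = round(iq_obs, 1))
    profiles <- cbind(profiles, as.data.frame(round(lik, 2)))
    profiles$gender <- gender
    profiles$handedness <- hand
    list(profiles = profiles, effect_scale = scale)
  })
}
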