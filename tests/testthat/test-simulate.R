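small_schedule <- function(seed = 1) {
  generate_protocol(n_sessions = 1, n_blocks = 1, seed = seed)
}

test_that("zero amplitudes and zero noise give an identically zero recording", {
  eff <- effect_spec(amplitude_scale = 0, jitter = 0)
  hemo <- simulate_hemodynamics(small_schedule(), eff, noise_spec(scale = 0),
                                seed = 1)
  expect_equal(max(abs(hemo[[1]]$conc)), 0)
})

test_that("simulation is bit-identical under the same seed", {
  a <- simulate_hemodynamics(small_schedule(), seed = 9)
  b <- simulate_hemodynamics(small_schedule(), seed = 9)
  expect_identical(a, b)
  c <- simulate_hemodynamics(small_schedule(), seed = 10)
  expect_false(identical(a[[1]]$conc, c[[1]]$conc))
})

test_that("total hemoglobin equals HbO plus Hb at every sample", {
  hemo <- fixture_hemo()
  expect_equal(hemo[[1]]$conc[, , "tHb"],
               hemo[[1]]$conc[, , "HbO"] + hemo[[1]]$conc[, , "Hb"])
})

test_that("cardiac-only noise peaks at the cardiac rate in the periodogram", {
  eff <- effect_spec(amplitude_scale = 0, jitter = 0)
  nz <- noise_spec(scale = 0)
  nz$cardiac_uM <- 0.2
  hemo <- simulate_hemodynamics(small_schedule(), eff, nz, seed = 4)
  x <- hemo[[1]]$conc[, 1, "HbO"]
  n <- length(x)
  sp <- Mod(stats::fft(x - mean(x)))[2:(n %/% 2)]^2
  f <- (2:(n %/% 2) - 1) * 31.25 / n
  expect_lt(abs(f[which.max(sp)] - 1.1), 31.25 / n + 1e-9)
})

test_that("sampling below the cardiac Nyquist rate is rejected", {
  expect_error(simulate_hemodynamics(small_schedule(), fs = 2, seed = 1),
               "twice the cardiac rate")
})

test_that("forward optics is exact: I0 at rest, round trip through the MBLL", {
  op <- optics_parameters()
  eff <- effect_spec(amplitude_scale = 0, jitter = 0)
  hemo0 <- simulate_hemodynamics(small_schedule(), eff, noise_spec(scale = 0),
                                 seed = 1)
  raw0 <- hemodynamics_to_intensity(hemo0, op, noise_spec(scale = 0), seed = 1)
  expect_equal(max(abs(raw0[[1]]$intensity - 1)), 0)

  hemo <- simulate_hemodynamics(small_schedule(), noise = noise_spec(scale = 0),
                                seed = 2)
  raw <- hemodynamics_to_intensity(hemo, op, noise_spec(scale = 0), seed = 2)
  od1 <- intensity_to_od(raw[[1]]$intensity[, , 1], op$I0)
  od2 <- intensity_to_od(raw[[1]]$intensity[, , 2], op$I0)
  rec <- mbll(od1, od2, op)
  expect_lt(max(abs(rec$HbO - hemo[[1]]$conc[, , "HbO"])), 1e-6)
  expect_lt(max(abs(rec$Hb - hemo[[1]]$conc[, , "Hb"])), 1e-6)
})

test_that("doubling the forward DPF halves concentrations recovered at the original DPF", {
  op <- optics_parameters()
  op2 <- optics_parameters(dpf = c(12, 12))
  hemo <- simulate_hemodynamics(small_schedule(), noise = noise_spec(scale = 0),
                                seed = 3)
  raw <- hemodynamics_to_intensity(hemo, op2, noise_spec(scale = 0), seed = 3)
  rec <- mbll(intensity_to_od(raw[[1]]$intensity[, , 1], 1),
              intensity_to_od(raw[[1]]$intensity[, , 2], 1), op)
  expect_equal(rec$HbO, 2 * hemo[[1]]$conc[, , "HbO"], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("non-positive reference intensity is rejected", {
  hemo <- fixture_hemo()
  op <- optics_parameters(I0 = 0)
  expect_error(hemodynamics_to_intensity(hemo, op, seed = 1), "I0")
})

test_that("participant profiles respect ranges and the IQ coupling direction", {
  spec0 <- participant_spec(n_participants = 200, iq_coupling = 0,
                            n_missing_iq = 0)
  sim0 <- simulate_participants(spec0, seed = 21)
  lik <- as.matrix(sim0$profiles[, c("tiredness", "concentration",
                                     "enjoyment", "ease", "comfort")])
  expect_true(all(lik >= 1 & lik <= 7))
  # no coupling: effect scale degenerate at 1, independent of IQ
  expect_true(all(sim0$effect_scale == 1))

  specn <- participant_spec(n_participants = 200, iq_coupling = -0.8,
                            n_missing_iq = 0)
  simn <- simulate_participants(specn, seed = 21)
  expect_lt(cor(simn$profiles$verbal_iq, simn$effect_scale,
                method = "spearman"), 0)
  # reproducible under seed
  expect_identical(simn, simulate_participants(specn, seed = 21))
})

test_that("requested missing IQ values are missing in the profile only", {
  sim <- simulate_participants(participant_spec(n_participants = 10,
                                                n_missing_iq = 1), seed = 2)
  expect_equal(sum(is.na(sim$profiles$verbal_iq)), 1)
  expect_true(all(is.finite(sim$effect_scale)))
})
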