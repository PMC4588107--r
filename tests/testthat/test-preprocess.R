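test_that("Chebyshev low-pass meets its design constraints", {
  filt <- design_lowpass()
  # unit DC gain (odd-order type I) and bounded passband ripple
  expect_equal(filter_gain(filt, 0), 1, tolerance = 1e-9)
  pass <- filter_gain(filt, seq(0.005, 0.1, by = 0.005))
  expect_true(all(20 * log10(pass) >= -0.1 - 1e-6))
  expect_true(all(20 * log10(pass) <= 1e-6))
  # stopband: at least 30 dB down from 0.5 Hz onward
  expect_lt(20 * log10(filter_gain(filt, 0.5)), -30)
  # stable: all poles strictly inside the unit circle
  expect_true(all(Mod(polyroot(rev(filt$a))) < 1))
})

test_that("digital stopband attenuation is at least the analog prototype's", {
  filt <- design_lowpass()
  eps <- sqrt(10^(0.1 / 10) - 1)
  t3 <- function(w) 4 * w^3 - 3 * w
  analog <- function(f) 1 / sqrt(1 + eps^2 * t3(f / 0.1)^2)
  for (f in c(0.5, 0.8, 1.1))
    expect_lte(filter_gain(filt, f), analog(f))
})

test_that("cascade filtering has unit steady-state gain and the designed attenuation", {
  filt <- design_lowpass()
  fs <- 31.25
  n <- round(120 * fs)
  t <- (0:(n - 1)) / fs
  settle <- (n %/% 2):n
  # constant input converges to the same constant
  yc <- nirsbci:::apply_cascade(filt, rep(2.5, n))
  expect_equal(yc[settle], rep(2.5, length(settle)), tolerance = 1e-6)
  # 1.1 Hz tone attenuated by >= 30 dB
  x1 <- sin(2 * pi * 1.1 * t)
  y1 <- nirsbci:::apply_cascade(filt, x1)
  rms <- function(v) sqrt(mean(v^2))
  expect_lt(20 * log10(rms(y1[settle]) / rms(x1[settle])), -30)
  # 0.05 Hz tone passes within the ripple budget
  x2 <- sin(2 * pi * 0.05 * t)
  y2 <- nirsbci:::apply_cascade(filt, x2)
  db <- 20 * log10(rms(y2[settle]) / rms(x2[settle]))
  expect_gt(db, -0.1 - 0.02)
  expect_lt(db, 0.02)
})

test_that("filtering a recording preserves structure and the tHb identity", {
  hemo <- fixture_hemo()
  filt <- design_lowpass()
  out <- filter_recording(hemo, filt)
  expect_equal(dim(out[[1]]$conc), dim(hemo[[1]]$conc))
  expect_equal(out[[1]]$conc[, , "tHb"],
               out[[1]]$conc[, , "HbO"] + out[[1]]$conc[, , "Hb"])
  expect_error(filter_recording(hemo, design_lowpass(filter_spec(fs = 10))),
               "designed for")
})

test_that("segmentation yields 24 epochs of 625 samples per default block", {
  hemo <- fixture_hemo()
  ep <- segment_trials(hemo)
  expect_length(ep, 24)
  expect_equal(dim(ep[[1]]$conc), c(625, 9, 3))
  expect_equal(round(20 * 31.25), 625)
  # referencing: first sample is zero everywhere
  expect_equal(max(abs(ep[[5]]$conc[1, , ])), 0)
})

test_that("exclusions drop the listed trials and late onsets error", {
  hemo <- fixture_hemo()
  tasks <- vapply(segment_trials(hemo), `[[`, "", "task")
  excl_iv <- which(tasks == tasks[1])[1:4]
  excl <- data.frame(session = 1, block = 1, interval = excl_iv)
  kept <- segment_trials(hemo, exclusions = excl)
  expect_length(kept, 20)
  kept_tasks <- vapply(kept, `[[`, "", "task")
  expect_equal(sum(kept_tasks == tasks[1]), sum(tasks == tasks[1]) - 4)

  short <- hemo
  short[[1]]$conc <- short[[1]]$conc[1:1000, , , drop = FALSE]
  expect_error(segment_trials(short), "past end")
})

test_that("epochs are exact onset-aligned slices of the filtered record", {
  hemo <- fixture_hemo()
  full <- filter_recording(hemo, design_lowpass())
  eps <- segment_trials(full, reference = FALSE)
  for (k in c(1, 12, 24)) {
    i0 <- floor(eps[[k]]$onset_s * 31.25) + 1  # independent index arithmetic
    expect_equal(eps[[k]]$conc, full[[1]]$conc[i0:(i0 + 624), , , drop = FALSE])
  }
  # epoch label multiset is fixed by the schedule regardless of filtering
  expect_equal(sort(vapply(eps, `[[`, "", "task")),
               sort(vapply(segment_trials(hemo), `[[`, "", "task")))
})
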