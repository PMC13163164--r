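# Gaussian R-spike train at the given beat times (mV).
make_ecg <- function(beat_times, duration_s, fs, amp = 1) {
  n <- round(duration_s * fs)
  x <- numeric(n)
  tt <- seq(-0.05, 0.05, by = 1 / fs)
  spike <- amp * exp(-tt^2 / (2 * 0.012^2))
  for (b in beat_times) {
    i0 <- round((b - 0.05) * fs) + 1
    idx <- i0:(i0 + length(spike) - 1)
    ok <- idx >= 1 & idx <= n
    x[idx[ok]] <- x[idx[ok]] + spike[ok]
  }
  x
}

test_that("R-peaks of a regular train are found with low jitter", {
  fs <- 256
  beats <- seq(1, 59, by = 1)
  ecg <- make_ecg(beats, 60, fs)
  rp <- detect_r_peaks(zero_phase_bandpass(ecg, 0.5, 35, fs), fs)
  expect_true(length(rp$peak_times_s) >= 57 && length(rp$peak_times_s) <= 61)
  expect_true(all(abs(rp$rr_s - 1) < 0.010))
  jit <- vapply(rp$peak_times_s, function(p) min(abs(beats - p)), numeric(1))
  expect_lt(max(jit), 0.010)
})

test_that("a flat ECG yields no peaks, with a warning", {
  expect_warning(rp <- detect_r_peaks(numeric(5000), 256), "flat")
  expect_length(rp$peak_times_s, 0)
})

test_that("a missing beat doubles one RR interval", {
  fs <- 256
  beats <- setdiff(seq(1, 59, by = 1), 30)
  ecg <- make_ecg(beats, 60, fs)
  rp <- detect_r_peaks(zero_phase_bandpass(ecg, 0.5, 35, fs), fs)
  long <- rp$rr_s[rp$rr_s > 1.5]
  expect_length(long, 1)
  expect_lt(abs(long - 2), 0.02)
})

test_that("instantaneous HR reproduces beatwise 60/RR", {
  rp <- structure(list(peak_times_s = seq(0, 120, by = 1),
                       rr_s = rep(1, 120), fs = 256), class = "rpeak_series")
  hr <- derive_instantaneous_hr(rp)
  expect_true(all(abs(hr$hr_bpm - 60) < 1e-6))
  expect_equal(diff(hr$t_s)[1], 0.1, tolerance = 1e-12)

  rr_alt <- rep(c(0.8, 1.0), 60)
  rp2 <- structure(list(peak_times_s = cumsum(c(0, rr_alt)), rr_s = rr_alt,
                        fs = 256), class = "rpeak_series")
  hr2 <- derive_instantaneous_hr(rp2)
  expect_true(all(hr2$hr_bpm > 59 - 2 & hr2$hr_bpm < 76 + 2))
})

test_that("a gross RR outlier is excluded by the 10-SD rule", {
  rr <- rep(1, 600); rr[300] <- 30
  rp <- structure(list(peak_times_s = cumsum(c(0, rr)), rr_s = rr, fs = 256),
                  class = "rpeak_series")
  hr <- derive_instantaneous_hr(rp)
  expect_true(all(hr$hr_bpm > 55 & hr$hr_bpm < 65))
})

test_that("too few beats is an error", {
  rp <- structure(list(peak_times_s = 0:5, rr_s = rep(1, 5), fs = 256),
                  class = "rpeak_series")
  expect_error(derive_instantaneous_hr(rp), "10")
})

test_that("LF/HF decomposition recovers injected band components", {
  t <- seq(0, 600, by = 0.1)
  hr <- structure(list(t_s = t,
                       hr_bpm = 60 + 3 * sin(2 * pi * 0.1 * t) +
                         2 * sin(2 * pi * 0.3 * t),
                       lf = NULL, hf = NULL, fs = 10), class = "hr_series")
  hr <- decompose_hr(hr)
  core <- t > 60 & t < 540            # central 80%
  lf_amp <- sqrt(2) * sd(hr$lf[core])
  hf_amp <- sqrt(2) * sd(hr$hf[core])
  expect_lt(abs(lf_amp - 3), 0.15)
  expect_lt(abs(hf_amp - 2), 0.10)
  expect_lt(abs(mean(hr$lf)), 0.05)
  expect_lt(abs(mean(hr$hf)), 0.05)
})

test_that("constant HR decomposes to silence; sub-band drift is rejected", {
  t <- seq(0, 600, by = 0.1)
  hr_const <- structure(list(t_s = t, hr_bpm = rep(62, length(t)), fs = 10),
                        class = "hr_series")
  hr_const <- decompose_hr(hr_const)
  expect_lt(sqrt(mean(hr_const$lf^2)), 0.01)
  expect_lt(sqrt(mean(hr_const$hf^2)), 0.01)

  hr_drift <- structure(list(t_s = t, hr_bpm = 60 + 5 * sin(2 * pi * 0.02 * t),
                             fs = 10), class = "hr_series")
  hr_drift <- decompose_hr(hr_drift)
  core <- t > 60 & t < 540
  expect_lt(sqrt(mean(hr_drift$lf[core]^2)), 0.2 * 5)
})

test_that("band components carry faithful Hilbert phase", {
  t <- seq(0, 600, by = 0.1)
  hr <- structure(list(t_s = t,
                       hr_bpm = 60 + 3 * sin(2 * pi * 0.1 * t) +
                         2 * sin(2 * pi * 0.3 * t), fs = 10),
                  class = "hr_series")
  hr <- decompose_hr(hr)
  core <- which(t > 60 & t < 540)
  ph_lf <- instantaneous_phase(hr$lf, 10)
  true_lf <- clasphase:::wrap_deg(360 * 0.1 * t + 0)   # sin: +90 at peak
  expect_lt(max(abs(circ_diff(ph_lf[core], true_lf[core]))), 10)
  ph_hf <- instantaneous_phase(hr$hf, 10)
  true_hf <- clasphase:::wrap_deg(360 * 0.3 * t)
  expect_lt(max(abs(circ_diff(ph_hf[core], true_hf[core]))), 10)
})
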