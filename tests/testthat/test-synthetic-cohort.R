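small_cfg <- function(...) {
  args <- utils::modifyList(list(n_subjects = 2, duration_s = 900,
                                 fs_eeg = 64, fs_ecg = 64, seed = 123),
                            list(...))
  do.call(sim_config, args)
}

test_that("generation is deterministic given seed and subject", {
  cfg <- small_cfg()
  a <- generate_recording(cfg, 0)
  b <- generate_recording(cfg, 0)
  expect_identical(a$recording, b$recording)
  expect_identical(a$ground_truth, b$ground_truth)
  c_ <- generate_recording(cfg, 1)
  expect_false(identical(a$recording$eeg, c_$recording$eeg))
})

test_that("an ablated configuration yields a detector-silent background", {
  cfg <- small_cfg(noise_sd = 0, so_rate = 0, spindle_rate = 0,
                   evoked_base_amp = 0, evoked_gain_so = 0,
                   evoked_gain_lf = 0, evoked_gain_hf = 0,
                   spindle_prob_base = 0, spindle_prob_gain = 0,
                   artifact_rate_per_h = 0, hr_resp_amp = 0)
  sim <- generate_recording(cfg, 0)
  so_band <- zero_phase_bandpass(sim$recording$eeg, 0.5, 4, 64)
  expect_equal(nrow(detect_slow_oscillations(so_band, 64)), 0)
  # only the deterministic rhythm remains
  expect_lt(max(abs(sim$recording$eeg)), cfg$so_rhythm_amp * 1.2)
})

test_that("recording structure invariants hold", {
  sim <- generate_recording(small_cfg(), 0)
  rec <- sim$recording
  expect_equal(length(rec$hypnogram), ceiling(rec$duration_s / 30))
  expect_equal(length(rec$eeg) / rec$fs_eeg, length(rec$ecg) / rec$fs_ecg)
  expect_gte(mean(rec$hypnogram %in% c("N2", "N3")), 0.6)
  # every tone onset falls in an N2/N3 epoch
  ep <- floor(rec$tones_s / 30) + 1
  expect_true(all(rec$hypnogram[ep] %in% c("N2", "N3")))
})

test_that("derived instantaneous HR matches the configured mean", {
  cfg <- sim_config(n_subjects = 1, duration_s = 900, fs_eeg = 64,
                    fs_ecg = 128, hr_mean = 60, lf_amp = 3, hf_amp = 2,
                    hr_resp_amp = 0, seed = 5)
  sim <- generate_recording(cfg, 0)
  rp <- detect_r_peaks(zero_phase_bandpass(sim$recording$ecg, 0.5, 35, 128), 128)
  hr <- derive_instantaneous_hr(rp)
  expect_lt(abs(mean(hr$hr_bpm) - 60), 0.5)
})

test_that("HR spectral content concentrates at the configured LF/HF frequencies", {
  cfg <- sim_config(n_subjects = 1, duration_s = 1800, fs_eeg = 64,
                    fs_ecg = 128, hr_resp_amp = 0, seed = 6)
  sim <- generate_recording(cfg, 0)
  rp <- detect_r_peaks(zero_phase_bandpass(sim$recording$ecg, 0.5, 35, 128), 128)
  hr <- derive_instantaneous_hr(rp)
  psd <- welch_psd(hr$hr_bpm - mean(hr$hr_bpm), 10, seg_s = 300)
  lf_sel <- psd$freq >= 0.04 & psd$freq <= 0.15
  hf_sel <- psd$freq > 0.15 & psd$freq <= 0.4
  expect_lt(abs(psd$freq[lf_sel][which.max(psd$power[lf_sel])] - 0.1), 0.01 + 1e-9)
  expect_lt(abs(psd$freq[hf_sel][which.max(psd$power[hf_sel])] - 0.25), 0.01 + 1e-9)
})

test_that("tone scheduling respects interval bounds and stages", {
  cfg <- small_cfg()
  hyp_n3 <- rep("N3", 120)
  set.seed(1)
  tones <- schedule_tones(cfg, hyp_n3)
  expect_true(length(tones) >= 120 && length(tones) <= 240)
  expect_true(all(diff(tones) >= 15 & diff(tones) <= 30))
  expect_warning(none <- schedule_tones(cfg, rep("W", 120)), "N2/N3")
  expect_length(none, 0)
  # 50% N3 in contiguous blocks: within-block gaps stay in [15, 30]
  hyp_mix <- rep(c(rep("N3", 60), rep("W", 60)), 2)
  set.seed(2)
  tmix <- schedule_tones(cfg, hyp_mix)
  same_block <- floor(tmix[-1] / 1800) == floor(tmix[-length(tmix)] / 1800)
  gaps <- diff(tmix)[same_block]
  expect_true(all(gaps >= 15 & gaps <= 30))
})

test_that("the injected amplitude law is exact", {
  cfg <- small_cfg()
  eeg <- numeric(64 * 60)
  phases <- data.frame(phi_so = c(75, 75, -105), phi_lf = c(60, 0, 60),
                       phi_hf = c(-120, 0, -120))
  # all gains zero: every tone gets the base amplitude exactly
  cfg0 <- small_cfg(evoked_gain_so = 0, evoked_gain_lf = 0, evoked_gain_hf = 0)
  inj0 <- inject_evoked_responses(eeg, 64, c(5, 20, 35), phases, cfg0)
  expect_equal(inj0$amp_uv, rep(cfg0$evoked_base_amp, 3))
  # optimum phases: base + sum of gains
  inj <- inject_evoked_responses(eeg, 64, c(5, 20, 35), phases, cfg)
  expect_equal(inj$amp_uv[1],
               cfg$evoked_base_amp + cfg$evoked_gain_so + cfg$evoked_gain_lf +
                 cfg$evoked_gain_hf)
  # SO at its optimum, HR terms off-peak
  expect_equal(inj$amp_uv[2],
               cfg$evoked_base_amp + cfg$evoked_gain_so +
                 cfg$evoked_gain_lf * cos(-60 * pi / 180) +
                 cfg$evoked_gain_hf * cos(120 * pi / 180))
})

test_that("ground-truth amplitudes follow the cosine law to within 0.01%", {
  sim <- generate_recording(small_cfg(), 0)
  gt <- sim$ground_truth$tones
  d2r <- pi / 180
  fit <- stats::lm(amp_uv ~ cos((phi_so - 75) * d2r) + cos((phi_lf - 60) * d2r) +
                     cos((phi_hf + 120) * d2r), data = gt)
  expect_lt(abs(coef(fit)[2] - 20), 0.01 * 20)
  expect_lt(abs(coef(fit)[3] - 10), 0.01 * 10)
  expect_lt(abs(coef(fit)[4] - 10), 0.01 * 10)
})

test_that("injected slow oscillations are recoverable at low noise", {
  cfg <- sim_config(n_subjects = 1, duration_s = 900, fs_eeg = 128,
                    fs_ecg = 64, noise_sd = 3, so_amp_mean = 180,
                    so_amp_sd = 8, so_rate = 6, spindle_rate = 0,
                    arousal_rate_per_h = 0, artifact_rate_per_h = 0,
                    evoked_base_amp = 0, evoked_gain_so = 0,
                    evoked_gain_lf = 0, evoked_gain_hf = 0,
                    hr_resp_amp = 0, seed = 9)
  sim <- generate_recording(cfg, 0)
  so_band <- zero_phase_bandpass(sim$recording$eeg, 0.5, 4, 128)
  det <- detect_slow_oscillations(so_band, 128)
  gt <- sim$ground_truth$so_events
  big <- gt[gt$amp_uv >= 160, ]
  hit <- vapply(seq_len(nrow(big)), function(i) {
    any(abs(det$start_s - big$start_s[i]) < 0.4)
  }, logical(1))
  expect_gte(mean(hit), 0.95)
})

test_that("recordings and configurations survive a text round-trip", {
  cfg <- small_cfg(duration_s = 120)
  sim <- generate_recording(cfg, 0)
  d <- file.path(tempdir(), "rec_roundtrip")
  write_recording(sim$recording, d)
  back <- read_recording(d)
  expect_equal(back$eeg, sim$recording$eeg, tolerance = 1e-6)
  expect_identical(back$hypnogram, sim$recording$hypnogram)
  expect_equal(back$tones_s, sim$recording$tones_s, tolerance = 1e-6)
  yml <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, yml)
  cfg2 <- read_sim_config(yml)
  expect_equal(unclass(cfg2), unclass(cfg))
  unlink(d, recursive = TRUE); unlink(yml)
})

test_that("invalid configurations name the offending field", {
  expect_error(sim_config(tone_interval_min = 30, tone_interval_max = 15),
               "tone_interval_min")
  expect_error(sim_config(preferred_phase_so = 200), "preferred_phase_so")
  expect_error(sim_config(spindle_freq = 20), "spindle_freq")
  expect_error(sim_config(hr_mean = -5), "hr_mean")
  expect_error(generate_recording(small_cfg(), 7), "subject_index")
})
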