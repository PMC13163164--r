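# Minimal hand-built recording context: 10 minutes, all N3 except where
# noted, no artifacts, fs 64.
trial_ctx <- function(hyp = rep("N3", 20), fs = 64, dur = 600) {
  list(hyp = hyp, fs = fs, dur = dur,
       mask = rep(FALSE, dur * fs),
       arousals = data.frame(start_s = numeric(0), end_s = numeric(0)))
}

test_that("stage, artifact and arousal rules gate STIM selection", {
  ctx <- trial_ctx()
  ctx$hyp[3] <- "N1"                       # epoch 3 = 60-90 s
  ctx$mask[150 * ctx$fs + 1:10] <- TRUE    # artifact near 150 s
  ctx$arousals <- data.frame(start_s = 305, end_s = 308)
  tones <- c(75, 150.2, 300, 450)
  kept <- select_stim_tones(tones, ctx$hyp, ctx$mask, ctx$fs, ctx$arousals, ctx$dur)
  expect_identical(kept$onset_s, 450)      # N1, artifact, arousal all excluded
  # a tone within 10 s of the N1 epoch is also excluded (window rule)
  kept2 <- select_stim_tones(c(95, 120), ctx$hyp, ctx$mask, ctx$fs,
                             ctx$arousals, ctx$dur)
  expect_identical(kept2$onset_s, 120)
})

test_that("UNSTIM windows come from tone-free gaps of at least 20 s", {
  ctx <- trial_ctx()
  tones <- c(100, 125)                     # 25-s gap -> midpoint 112.5
  un <- find_unstim_windows(tones, ctx$hyp, ctx$mask, ctx$fs, ctx$arousals,
                            ctx$dur)
  expect_true(112.5 %in% un$onset_s)
  tones2 <- c(100, 118)                    # 18-s gap: nothing
  un2 <- find_unstim_windows(tones2, ctx$hyp, ctx$mask, ctx$fs, ctx$arousals,
                             ctx$dur)
  expect_false(any(un2$onset_s > 100 & un2$onset_s < 118))
  # a single 60-s clean block yields exactly one midpoint window
  tones3 <- c(200, 260)
  un3 <- find_unstim_windows(tones3, ctx$hyp, ctx$mask, ctx$fs, ctx$arousals,
                             ctx$dur)
  expect_identical(sum(un3$onset_s > 200 & un3$onset_s < 260), 1L)
  expect_true(230 %in% un3$onset_s)
})

test_that("trials require an evoked slow oscillation within the latency bound", {
  so <- data.frame(start_s = c(10.5, 41), end_s = c(11.7, 42.2),
                   duration_s = c(1.2, 1.2), trough_s = c(11.2, 41.5),
                   trough_uv = c(-120, -95), peak_s = c(11.5, 42),
                   peak_uv = c(100, 60), p2p_uv = c(220, 155))
  trials <- data.frame(onset_s = c(10, 37, 41.2), is_stim = TRUE)
  out <- require_evoked_so(trials, so)
  expect_equal(out$onset_s, c(10, 41.2))
  expect_equal(out$so_p2p_uv[1], 220)
  # first SO wins when two fall inside the bound
  so2 <- rbind(so, data.frame(start_s = 11.9, end_s = 13, duration_s = 1.1,
                              trough_s = 11.9 + 0.5, trough_uv = -100,
                              peak_s = 12.8, peak_uv = 70, p2p_uv = 170))
  out2 <- require_evoked_so(data.frame(onset_s = 10.5, is_stim = TRUE), so2)
  expect_equal(out2$so_trough_s, 11.2)
})

test_that("trial responses quantify the attached oscillation and HR window", {
  fs <- 64
  set.seed(51)
  eeg <- rnorm(600 * fs, 0, 20)
  so <- data.frame(start_s = 100.4, end_s = 101.6, duration_s = 1.2,
                   trough_s = 101, trough_uv = -120, peak_s = 101.4,
                   peak_uv = 100, p2p_uv = 220)
  trials <- require_evoked_so(data.frame(onset_s = 100.2, is_stim = TRUE,
                                         subject_id = "S1"), so)
  hr <- structure(list(t_s = seq(0, 600, 0.1),
                       hr_bpm = rep(60, 6001), fs = 10), class = "hr_series")
  out <- compute_trial_responses(trials, eeg, fs, spindles = NULL, hr = hr)
  expect_equal(out$so_p2p_uv, 220)
  expect_equal(out$hr_p2p_bpm, 0)
  expect_false(out$spindle_flag)
  expect_true(is.finite(out$swa_norm))
})

test_that("STIM and UNSTIM windows never overlap on a processed cohort", {
  cfg <- sim_config(n_subjects = 1, duration_s = 1500, fs_eeg = 64,
                    fs_ecg = 64, seed = 77)
  sim <- generate_recording(cfg, 0)
  res <- process_recording(sim$recording, do_spindles = FALSE,
                           do_conditions = FALSE, do_hr = FALSE)
  tr <- res$trials
  st <- tr$onset_s[tr$is_stim]
  un <- tr$onset_s[!tr$is_stim]
  if (length(st) && length(un)) {
    gaps <- outer(st, un, function(a, b) abs(a - b))
    expect_true(all(gaps >= 10))   # +/-10 s windows cannot overlap
  }
  # retained windows lie wholly inside clean N2/N3
  hyp <- sim$recording$hypnogram
  for (t0 in tr$onset_s) {
    eps <- (floor((t0 - 10) / 30) + 1):(floor((t0 + 10 - 1e-6) / 30) + 1)
    expect_true(all(hyp[eps] %in% c("N2", "N3")))
  }
  # funnel counts never increase along the chain
  f <- res$funnel
  expect_lte(f["stim_retained"], f["stim_stage_artifact_pass"])
  expect_lte(f["stim_stage_artifact_pass"], f["tones_total"])
  expect_lte(f["unstim_retained"], f["unstim_candidates"])
})

test_that("most clean-sleep tones become retained trials at high amplitude", {
  cfg <- sim_config(n_subjects = 1, duration_s = 1800, fs_eeg = 128,
                    fs_ecg = 64, evoked_base_amp = 180, noise_sd = 6,
                    arousal_rate_per_h = 0, artifact_rate_per_h = 0,
                    hr_resp_amp = 0, seed = 13)
  sim <- generate_recording(cfg, 0)
  res <- process_recording(sim$recording, do_spindles = FALSE,
                           do_conditions = FALSE, do_hr = FALSE)
  f <- res$funnel
  expect_gte(f["stim_retained"] / f["stim_stage_artifact_pass"], 0.9)
})
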