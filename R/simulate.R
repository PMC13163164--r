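# --- low-level building blocks -------------------------------------------

# 1/f^slope coloured noise with unit variance, via FFT spectral shaping.
colored_noise <- function(n, fs, slope) {
  if (n < 2) return(numeric(n))
  white <- stats::rnorm(n)
  if (slope == 0) return(white)
  X <- stats::fft(white)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)                      # two-sided frequency axis
  g <- c(0, f[-1]^(-slope / 2))
  x <- Re(stats::fft(X * g, inverse = TRUE) / n)
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

# Asymmetric single-cycle slow-oscillation waveform: a deep narrow trough
# followed by a shallow wide peak, peak-to-peak amplitude `amp`, core
# duration `dur_s`. Trough depth is `trough_frac * amp` over a width of
# `(1 - trough_frac) * dur_s`, so the two half-waves have equal areas and
# the waveform survives high-pass filtering without baseline shifts.
# Small equal-area lead-in (+) and tail (-) lobes bracket the core cycle,
# pinning the downward zero crossings that delimit the event for the
# detector to the waveform's own boundaries (mimicking the P200-like
# positivity that precedes an evoked K-complex).
so_waveform <- function(amp, dur_s, fs, trough_frac = 0.57,
                        lobe_frac = 0.15, lobe_amp = NULL, echo_frac = 0) {
  if (is.null(lobe_amp)) lobe_amp <- min(25, max(12, 0.1 * amp))
  half_sine <- function(a, w) {
    m <- max(2L, round(w * fs))
    a * sin(pi * seq(0, 1, length.out = m))
  }
  core <- c(half_sine(-trough_frac * amp, (1 - trough_frac) * dur_s),
            half_sine((1 - trough_frac) * amp, trough_frac * dur_s))
  # optional trailing echo cycle (evoked delta burst at reduced amplitude)
  echo <- if (echo_frac > 0) {
    c(half_sine(-trough_frac * amp * echo_frac, (1 - trough_frac) * dur_s),
      half_sine((1 - trough_frac) * amp * echo_frac, trough_frac * dur_s))
  } else numeric(0)
  c(half_sine(lobe_amp, lobe_frac * dur_s), core, echo,
    half_sine(-lobe_amp, lobe_frac * dur_s))
}

# Peak-to-peak gain of the standard 0.5-4 Hz zero-phase filtering on the
# slow-oscillation waveform shape, per core duration. Injected waveforms
# are pre-scaled by the inverse so that the amplitude the analysis
# measures equals the configured peak-to-peak value.
so_filter_gain <- function(dur_s, fs, trough_frac = 0.57, lobe_frac = 0.15,
                           echo_frac = 0) {
  vapply(dur_s, function(d) {
    w <- so_waveform(100, d, fs, trough_frac, lobe_frac, echo_frac = echo_frac)
    pad <- numeric(round(5 * fs))
    wf <- zero_phase_bandpass(c(pad, w, pad), 0.5, 4, fs)
    (max(wf) - min(wf)) / 100
  }, numeric(1))
}

# Splice `wave` into `layer` starting at sample `start_idx`, crossfading
# over `ramp_s` at both ends so the background is replaced, not summed.
crossfade_splice <- function(layer, start_idx, wave, fs, ramp_s = 0.1) {
  n <- length(layer)
  m <- length(wave)
  if (start_idx > n || start_idx + m - 1L < 1L) return(layer)
  a <- max(1L, start_idx)
  b <- min(n, start_idx + m - 1L)
  wseg <- wave[(a - start_idx + 1L):(b - start_idx + 1L)]
  ramp <- min(length(wseg) %/% 2L, max(1L, round(ramp_s * fs)))
  w <- rep(1, length(wseg))
  if (ramp > 1) {
    up <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = ramp)))
    w[seq_len(ramp)] <- up
    w[(length(wseg) - ramp + 1L):length(wseg)] <- rev(up)
  }
  layer[a:b] <- (1 - w) * layer[a:b] + w * wseg
  layer
}

# Poisson event times over [0, duration_s) at `rate_per_min`, keeping only
# events whose epoch is N2 or N3.
poisson_times_n2n3 <- function(rate_per_min, duration_s, hypnogram) {
  if (rate_per_min <= 0) return(numeric(0))
  n_exp <- rate_per_min / 60 * duration_s
  times <- cumsum(stats::rexp(ceiling(n_exp + 6 * sqrt(n_exp) + 10),
                              rate = rate_per_min / 60))
  times <- times[times < duration_s]
  times[hypnogram[epoch_of(times)] %in% c("N2", "N3")]
}

epoch_of <- function(t_s) pmin(floor(t_s / 30) + 1L, .Machine$integer.max)

# Simple block-structured sleep architecture: a short wake/N1 onset, then
# repeating cycles of N2 -> N3 -> N2 -> REM. Guarantees >= 60% N2/N3.
make_hypnogram <- function(duration_s) {
  n_epochs <- ceiling(duration_s / 30)
  stages <- c("W", "N1", "N1")
  while (length(stages) < n_epochs) {
    cyc <- c(rep("N2", sample(8:14, 1)),
             rep("N3", sample(30:50, 1)),
             rep("N2", sample(6:10, 1)),
             rep("R", sample(6:10, 1)))
    stages <- c(stages, cyc)
  }
  stages[seq_len(n_epochs)]
}

#' Schedule tones at random intervals during N2/N3 sleep
#'
#' Successive candidate onsets differ by an independent uniform draw in
#' `[tone_interval_min, tone_interval_max]`; candidates whose 30-s epoch
#' is not N2 or N3 are dropped. Consumes the current RNG stream.
#'
#' @param config a [sim_config()].
#' @param hypnogram character vector of stages per 30-s epoch.
#' @return numeric vector of onset times (s); empty (with a warning) when
#'   the hypnogram contains no N2/N3 epochs.
#' @export
schedule_tones <- function(config, hypnogram) {
  if (length(hypnogram) == 0) stopf("empty hypnogram")
  if (!any(hypnogram %in% c("N2", "N3"))) {
    warnf("hypnogram contains no N2/N3 epochs; no tones scheduled")
    return(numeric(0))
  }
  duration_s <- length(hypnogram) * 30
  n_max <- ceiling(duration_s / config$tone_interval_min) + 1L
  gaps <- stats::runif(n_max, config$tone_interval_min, config$tone_interval_max)
  onsets <- cumsum(gaps)
  onsets <- onsets[onsets < duration_s - 1]
  onsets[hypnogram[epoch_of(onsets)] %in% c("N2", "N3")]
}

# True (noise-free) oscillation phases at arbitrary times, under the
# quadrature convention (+90 deg at the peak of a sine).
true_phases <- function(t_s, freq_hz, phase0_rad) {
  wrap_deg((freq_hz * t_s * 360) + phase0_rad * 180 / pi)
}

#' Inject tone-evoked slow-oscillation responses into an EEG trace
#'
#' For each tone, a single-cycle slow-oscillation waveform (trough then
#' peak, one cycle of the configured SO frequency) is spliced into the EEG
#' at `onset + evoked_latency_s`. Its peak-to-peak amplitude follows the
#' additive cosine law of the configured gains and preferred phases,
#' clipped at zero from below.
#'
#' @param eeg EEG trace (microvolts) at `fs`.
#' @param fs sampling rate (Hz).
#' @param tones_s tone onset times (s).
#' @param phases data.frame with columns `phi_so`, `phi_lf`, `phi_hf`
#'   (degrees), one row per tone.
#' @param config a [sim_config()].
#' @return list with `eeg` (modified trace) and `amp_uv` (injected
#'   peak-to-peak amplitude per tone).
#' @export
inject_evoked_responses <- function(eeg, fs, tones_s, phases, config) {
  if (length(tones_s) != nrow(phases)) stopf("phases must have one row per tone")
  d2r <- pi / 180
  amp <- config$evoked_base_amp +
    config$evoked_gain_so * cos((phases$phi_so - config$preferred_phase_so) * d2r) +
    config$evoked_gain_lf * cos((phases$phi_lf - config$preferred_phase_lf) * d2r) +
    config$evoked_gain_hf * cos((phases$phi_hf - config$preferred_phase_hf) * d2r)
  amp <- pmax(amp, 0)
  dur <- 1 / config$so_freq
  echo <- config$evoked_echo_frac
  g <- if (any(amp > 0)) so_filter_gain(dur, fs, config$so_trough_frac) else 1
  n <- length(eeg)
  for (i in seq_along(tones_s)) {
    if (amp[i] <= 0) next
    # core cycle replaces the ongoing background (crossfade splice)...
    wave <- so_waveform(amp[i] / g, dur, fs, config$so_trough_frac)
    start_idx <- round((tones_s[i] + config$evoked_latency_s) * fs) + 1L
    eeg <- crossfade_splice(eeg, start_idx, wave, fs)
    # ...while the echo cycle (evoked delta burst) adds on top of it, so
    # stimulated windows gain slow-wave power
    if (echo > 0) {
      ew <- so_waveform(echo * amp[i] / g, dur, fs, config$so_trough_frac,
                        lobe_amp = 1e-9)
      e0 <- start_idx + length(wave) - 1L
      e1 <- min(n, e0 + length(ew) - 1L)
      if (e0 >= 1L && e0 <= n) {
        eeg[e0:e1] <- eeg[e0:e1] + ew[seq_len(e1 - e0 + 1L)]
      }
    }
  }
  list(eeg = eeg, amp_uv = amp)
}

# Tukey-windowed spindle burst.
spindle_waveform <- function(amp, dur_s, freq, fs, phase0 = 0) {
  n <- max(8L, round(dur_s * fs))
  tau <- (seq_len(n) - 1L) / fs
  amp * sin(2 * pi * freq * tau + phase0) * tukey_window(n, 0.25)
}

# ECG beat template covering [-0.3, 0.45] s: P, Q, R, S, T deflections (mV).
ecg_template <- function(fs, r_amp = 1) {
  tt <- seq(-0.3, 0.45, by = 1 / fs)
  g <- function(mu, sd, a) a * exp(-(tt - mu)^2 / (2 * sd^2))
  list(wave = g(-0.2, 0.04, 0.08 * r_amp) + g(-0.03, 0.012, -0.1 * r_amp) +
         g(0, 0.012, r_amp) + g(0.03, 0.014, -0.15 * r_amp) +
         g(0.25, 0.06, 0.2 * r_amp),
       offset = round(0.3 * fs))
}

# --- the generator --------------------------------------------------------

#' Generate one synthetic polysomnography recording with ground truth
#'
#' Builds a synchronized EEG + ECG pair with a block-structured hypnogram,
#' arousal and artifact intervals, a tone train during N2/N3, and
#' tone-evoked slow oscillations whose amplitude depends on the true
#' instantaneous phases of the EEG slow-oscillation rhythm and the LF/HF
#' heart-rate modulation. Deterministic given `(config$seed,
#' subject_index)`; the caller's RNG state is left untouched.
#'
#' The EEG slow-oscillation band is modelled as a weak continuous rhythm
#' at `so_freq` (the phase carrier) into which spontaneous
#' slow-oscillation events -- phase-aligned to the rhythm -- and
#' tone-evoked waveforms are spliced with short crossfades; 1/f background
#' noise and spindle bursts are added on top.
#'
#' @param config a [sim_config()].
#' @param subject_index zero-based subject index (< `n_subjects`).
#' @return list with elements `recording` (class `psg_recording`: `eeg`,
#'   `ecg`, `fs_eeg`, `fs_ecg`, `hypnogram`, `arousals`, `tones_s`,
#'   `subject_id`, `duration_s`) and `ground_truth` (injected events, true
#'   per-tone phases and amplitudes, per-subject oscillator parameters).
#' @export
generate_recording <- function(config, subject_index = 0) {
  validate_sim_config(config)
  if (subject_index < 0 || subject_index >= config$n_subjects) {
    stopf("subject_index must lie in [0, n_subjects)")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed((config$seed * 1009L + subject_index * 7919L) %% 2147483647L)

  fs <- config$fs_eeg
  duration_s <- config$duration_s
  n <- round(duration_s * fs)
  t_eeg <- (seq_len(n) - 1L) / fs

  hypnogram <- make_hypnogram(duration_s)
  n2n3_epoch <- hypnogram %in% c("N2", "N3")

  # arousals: uniform starts, 3-10 s, anywhere in the night
  n_arous <- stats::rpois(1, config$arousal_rate_per_h * duration_s / 3600)
  arousals <- data.frame(start_s = numeric(0), end_s = numeric(0))
  if (n_arous > 0) {
    a0 <- sort(stats::runif(n_arous, 0, duration_s - 10))
    arousals <- data.frame(start_s = a0, end_s = a0 + stats::runif(n_arous, 3, 10))
  }

  # oscillator initial phases (per subject)
  th_so <- stats::runif(1, 0, 2 * pi)
  th_lf <- stats::runif(1, 0, 2 * pi)
  th_hf <- stats::runif(1, 0, 2 * pi)

  tones_s <- schedule_tones(config, hypnogram)

  # --- EEG layers ---
  so_layer <- config$so_rhythm_amp * sin(2 * pi * config$so_freq * t_eeg + th_so)

  # spontaneous SOs, aligned to the rhythm's downward zero crossing
  so_times <- poisson_times_n2n3(config$so_rate, duration_s, hypnogram)
  so_events <- data.frame(start_s = numeric(0), duration_s = numeric(0),
                          amp_uv = numeric(0))
  if (length(so_times) > 0) {
    psi <- (config$so_freq * so_times * 2 * pi + th_so) %% (2 * pi)
    t_dz <- so_times + ((pi - psi) %% (2 * pi)) / (2 * pi * config$so_freq)
    amp <- pmax(20, stats::rnorm(length(so_times), config$so_amp_mean,
                                 config$so_amp_sd))
    dur <- stats::runif(length(so_times), 1.05, 1.45)
    keep <- t_dz + dur < duration_s
    so_events <- data.frame(start_s = t_dz, duration_s = dur, amp_uv = amp)[keep, ]
    gain_grid <- seq(1.0, 1.5, by = 0.05)
    gains <- so_filter_gain(gain_grid, fs, config$so_trough_frac)
    for (i in seq_len(nrow(so_events))) {
      g <- stats::approx(gain_grid, gains, so_events$duration_s[i], rule = 2)$y
      wave <- so_waveform(so_events$amp_uv[i] / g, so_events$duration_s[i], fs,
                          config$so_trough_frac)
      so_layer <- crossfade_splice(so_layer,
                                   round(so_events$start_s[i] * fs) + 1L,
                                   wave, fs)
    }
  }

  # tone-evoked SOs (true phases from the noise-free oscillators)
  tone_phases <- data.frame(
    phi_so = true_phases(tones_s, config$so_freq, th_so),
    phi_lf = true_phases(tones_s, config$lf_freq, th_lf),
    phi_hf = true_phases(tones_s, config$hf_freq, th_hf)
  )
  inj <- inject_evoked_responses(so_layer, fs, tones_s, tone_phases, config)
  so_layer <- inj$eeg

  # spindles: spontaneous plus SO-phase-coupled evoked bursts
  spindle_layer <- numeric(n)
  sp_times <- poisson_times_n2n3(config$spindle_rate, duration_s, hypnogram)
  sp_df <- data.frame(start_s = numeric(0), duration_s = numeric(0),
                      evoked = logical(0))
  add_spindle <- function(t0, dur) {
    wave <- spindle_waveform(config$spindle_amp, dur, config$spindle_freq, fs,
                             stats::runif(1, 0, 2 * pi))
    i0 <- round(t0 * fs) + 1L
    i1 <- min(n, i0 + length(wave) - 1L)
    if (i0 >= 1L && i0 <= n) {
      spindle_layer[i0:i1] <<- spindle_layer[i0:i1] + wave[seq_len(i1 - i0 + 1L)]
    }
  }
  if (config$spindle_amp > 0) {
    for (t0 in sp_times) {
      dur <- stats::runif(1, 0.5, 1.5)
      add_spindle(t0, dur)
      sp_df <- rbind(sp_df, data.frame(start_s = t0, duration_s = dur,
                                       evoked = FALSE))
    }
  }
  # SO-coupled spindles: every spontaneous SO spawns one with the base
  # probability; evoked SOs with the base plus the SO-phase-dependent gain,
  # so STIM and UNSTIM share the same coupling baseline.
  if (config$spindle_amp > 0 && config$spindle_prob_base > 0 &&
      nrow(so_events) > 0) {
    trough_lag_sp <- (0.15 + (1 - config$so_trough_frac) / 2) * so_events$duration_s
    draw_sp <- stats::runif(nrow(so_events))
    for (i in seq_len(nrow(so_events))) {
      if (draw_sp[i] < config$spindle_prob_base) {
        dur <- stats::runif(1, 0.5, 1.0)
        t0 <- so_events$start_s[i] + trough_lag_sp[i] + stats::runif(1, 0.2, 0.6)
        add_spindle(t0, dur)
        sp_df <- rbind(sp_df, data.frame(start_s = t0, duration_s = dur,
                                         evoked = FALSE))
      }
    }
  }
  evoked_spindle <- rep(FALSE, length(tones_s))
  if (config$spindle_amp > 0 && length(tones_s) > 0 &&
      (config$spindle_prob_base > 0 || config$spindle_prob_gain > 0)) {
    d2r <- pi / 180
    p_sp <- pmin(1, pmax(0, config$spindle_prob_base + config$spindle_prob_gain *
                              cos((tone_phases$phi_so - config$preferred_phase_so) * d2r)))
    draw <- stats::runif(length(tones_s))
    trough_lag <- config$evoked_latency_s +
      (0.15 + (1 - config$so_trough_frac) / 2) / config$so_freq
    for (i in seq_along(tones_s)) {
      if (draw[i] < p_sp[i] && inj$amp_uv[i] > 0) {
        evoked_spindle[i] <- TRUE
        dur <- stats::runif(1, 0.5, 1.0)
        t0 <- tones_s[i] + trough_lag + stats::runif(1, 0.2, 0.6)
        add_spindle(t0, dur)
        sp_df <- rbind(sp_df, data.frame(start_s = t0, duration_s = dur,
                                         evoked = TRUE))
      }
    }
  }

  background <- config$noise_sd * colored_noise(n, fs, config$background_slope)

  # occasional high-amplitude artifacts to exercise exclusion logic
  artifact_layer <- numeric(n)
  n_art <- stats::rpois(1, config$artifact_rate_per_h * duration_s / 3600)
  artifacts <- data.frame(start_s = numeric(0), end_s = numeric(0))
  if (n_art > 0) {
    a0 <- stats::runif(n_art, 0, duration_s - 1)
    for (t0 in a0) {
      i0 <- round(t0 * fs) + 1L
      m <- round(0.5 * fs)
      i1 <- min(n, i0 + m - 1L)
      artifact_layer[i0:i1] <- artifact_layer[i0:i1] +
        2000 * sample(c(-1, 1), 1) * hann_window(i1 - i0 + 1L)
    }
    artifacts <- data.frame(start_s = a0, end_s = a0 + 0.5)
  }

  eeg <- background + so_layer + spindle_layer + artifact_layer

  # --- ECG: beat train with LF/HF-modulated RR intervals ---
  # plus a tone-evoked heart-rate transient whose size depends on the SO
  # phase at tone onset (largest on the ascending positive phase)
  fs_ecg <- config$fs_ecg
  n_ecg <- round(duration_s * fs_ecg)
  bump_fs <- 10
  bump_grid <- numeric(round(duration_s * bump_fs) + 1L)
  if (config$hr_resp_amp > 0 && length(tones_s) > 0) {
    d2r <- pi / 180
    a_resp <- config$hr_resp_amp *
      (1 + cos((tone_phases$phi_so - config$hr_resp_phase) * d2r)) / 2
    bump <- sin(pi * seq(0, 1, length.out = 5 * bump_fs + 1L))^2
    for (i in seq_along(tones_s)) {
      i0 <- round(tones_s[i] * bump_fs) + 1L
      i1 <- min(length(bump_grid), i0 + length(bump) - 1L)
      bump_grid[i0:i1] <- bump_grid[i0:i1] + a_resp[i] * bump[seq_len(i1 - i0 + 1L)]
    }
  }
  hr_at <- function(t) {
    config$hr_mean + config$lf_amp * sin(2 * pi * config$lf_freq * t + th_lf) +
      config$hf_amp * sin(2 * pi * config$hf_freq * t + th_hf) +
      bump_grid[pmin(length(bump_grid), round(t * bump_fs) + 1L)]
  }
  beats <- numeric(ceiling(duration_s * (config$hr_mean + config$lf_amp +
                                           config$hf_amp) / 60) + 10L)
  tb <- 0.4
  nb <- 0L
  while (tb < duration_s - 0.5) {
    nb <- nb + 1L
    beats[nb] <- tb
    # RR matched to the mid-interval rate (one fixed-point refinement), so
    # each interval's mean rate equals the modulation at its midpoint
    rr <- 60 / hr_at(tb)
    rr <- 60 / hr_at(tb + rr / 2)
    tb <- tb + rr
  }
  beats <- beats[seq_len(nb)]
  tmpl <- ecg_template(fs_ecg)
  ecg <- stats::rnorm(n_ecg, 0, 0.01)
  m <- length(tmpl$wave)
  for (b in beats) {
    i0 <- round(b * fs_ecg) + 1L - tmpl$offset
    i1 <- i0 + m - 1L
    if (i0 >= 1L && i1 <= n_ecg) ecg[i0:i1] <- ecg[i0:i1] + tmpl$wave
  }

  recording <- structure(list(
    subject_id = sprintf("S%03d", subject_index),
    eeg = eeg, ecg = ecg, fs_eeg = fs, fs_ecg = fs_ecg,
    duration_s = duration_s, hypnogram = hypnogram,
    arousals = arousals, tones_s = tones_s
  ), class = "psg_recording")

  ground_truth <- list(
    subject_id = recording$subject_id,
    tones = cbind(data.frame(onset_s = tones_s), tone_phases,
                  amp_uv = inj$amp_uv, evoked_spindle = evoked_spindle),
    so_events = so_events,
    spindles = sp_df,
    beats_s = beats,
    artifacts = artifacts,
    oscillators = list(so = c(freq = config$so_freq, phase0 = th_so),
                       lf = c(freq = config$lf_freq, phase0 = th_lf),
                       hf = c(freq = config$hf_freq, phase0 = th_hf))
  )
  list(recording = recording, ground_truth = ground_truth)
}

#' @export
print.psg_recording <- function(x, ...) {
  cat("<psg_recording>", x$subject_id, ":", x$duration_s, "s,",
      length(x$tones_s), "tones,", nrow(x$arousals), "arousals;",
      "stages:", paste(names(table(x$hypnogram)), table(x$hypnogram),
                       collapse = " ", sep = ":"), "\n")
  invisible(x)
}

#' Write a recording to plain-text files / read it back
#'
#' Signals are written as CSV (`eeg.csv`, `ecg.csv` with a time column),
#' the hypnogram as `hypnogram.csv` (epoch_index, stage), arousals and
#' tones as CSV event lists, and the metadata as JSON.
#'
#' @param recording a `psg_recording`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly; `read_recording` returns the
#'   reconstructed `psg_recording`.
#' @export
write_recording <- function(recording, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(t_s = (seq_along(recording$eeg) - 1) / recording$fs_eeg,
                              eeg_uv = recording$eeg),
                   file.path(dir, "eeg.csv"), row.names = FALSE)
  utils::write.csv(data.frame(t_s = (seq_along(recording$ecg) - 1) / recording$fs_ecg,
                              ecg_mv = recording$ecg),
                   file.path(dir, "ecg.csv"), row.names = FALSE)
  utils::write.csv(data.frame(epoch_index = seq_along(recording$hypnogram),
                              stage = recording$hypnogram),
                   file.path(dir, "hypnogram.csv"), row.names = FALSE)
  utils::write.csv(recording$arousals, file.path(dir, "arousals.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(onset_s = recording$tones_s),
                   file.path(dir, "tones.csv"), row.names = FALSE)
  jsonlite::write_json(list(subject_id = recording$subject_id,
                            fs_eeg = recording$fs_eeg,
                            fs_ecg = recording$fs_ecg,
                            duration_s = recording$duration_s),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_recording
#' @export
read_recording <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  structure(list(
    subject_id = meta$subject_id,
    eeg = utils::read.csv(file.path(dir, "eeg.csv"))$eeg_uv,
    ecg = utils::read.csv(file.path(dir, "ecg.csv"))$ecg_mv,
    fs_eeg = meta$fs_eeg, fs_ecg = meta$fs_ecg,
    duration_s = meta$duration_s,
    hypnogram = utils::read.csv(file.path(dir, "hypnogram.csv"))$stage,
    arousals = utils::read.csv(file.path(dir, "arousals.csv")),
    tones_s = utils::read.csv(file.path(dir, "tones.csv"))$onset_s
  ), class = "psg_recording")
}
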