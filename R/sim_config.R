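#' Simulation configuration for the synthetic polysomnography cohort
#'
#' Builds a validated configuration for [generate_recording()]. Defaults
#' encode the emulated study conditions: tones at random 15-30 s intervals
#' during N2/N3, an EEG slow-oscillation rhythm near 0.8 Hz with dense
#' spontaneous slow oscillations, 11-16 Hz spindles, LF/HF heart-rate
#' modulation, and tone-evoked slow oscillations whose amplitude follows
#' an additive cosine law of the three instantaneous phases with preferred
#' phases 75 deg (EEG SO), 60 deg (HR-LF) and -120 deg (HR-HF).
#'
#' The evoked amplitude law is
#' `amp = evoked_base_amp + sum_c evoked_gain_c * cos(phi_c - preferred_phase_c)`
#' over components `c` in (so, lf, hf), clipped at zero from below.
#'
#' @param n_subjects number of subjects in the cohort.
#' @param duration_s recording length per subject (s).
#' @param fs_eeg,fs_ecg sampling rates (Hz).
#' @param so_rate spontaneous slow-oscillation events per minute of N2/N3.
#' @param so_amp_mean,so_amp_sd spontaneous SO peak-to-peak amplitude
#'   distribution (microvolts).
#' @param so_freq slow-oscillation rhythm frequency (Hz).
#' @param so_rhythm_amp amplitude of the continuous background SO rhythm
#'   (microvolts); the phase carrier, too small to pass event detection.
#' @param so_trough_frac fraction of an SO's peak-to-peak amplitude taken
#'   by the trough (waveform asymmetry).
#' @param spindle_rate spontaneous spindles per minute of N2/N3.
#' @param spindle_freq spindle frequency in Hz, within 11-16.
#' @param spindle_amp spindle burst amplitude (microvolts).
#' @param spindle_prob_base,spindle_prob_gain probability law for a
#'   tone-evoked, SO-coupled spindle:
#'   `p = base + gain * cos(phi_so - preferred_phase_so)`, clipped to
#'   `[0, 1]`.
#' @param background_slope 1/f exponent of the EEG background noise.
#' @param hr_mean mean heart rate (bpm).
#' @param lf_freq,hf_freq LF and HF modulation frequencies (Hz), inside
#'   0.04-0.15 and 0.15-0.4 respectively.
#' @param lf_amp,hf_amp modulation amplitudes (bpm).
#' @param tone_interval_min,tone_interval_max uniform inter-tone interval
#'   bounds (s).
#' @param evoked_base_amp baseline evoked SO amplitude (microvolts p2p).
#' @param evoked_gain_so,evoked_gain_lf,evoked_gain_hf cosine gains
#'   (microvolts per unit cosine).
#' @param preferred_phase_so,preferred_phase_lf,preferred_phase_hf
#'   preferred phases (degrees, in `[-180, 180)`).
#' @param evoked_latency_s latency from tone onset to the start of the
#'   evoked waveform (s).
#' @param evoked_echo_frac relative amplitude of the trailing echo cycle
#'   of the evoked response (the evoked delta burst); 0 disables it.
#' @param hr_resp_amp peak tone-evoked heart-rate transient (bpm) at the
#'   most responsive SO phase; 0 disables the cardiac response.
#' @param hr_resp_phase SO phase (degrees) of the largest HR response.
#' @param noise_sd EEG background noise standard deviation (microvolts).
#' @param arousal_rate_per_h injected arousal rate.
#' @param artifact_rate_per_h injected high-amplitude artifact rate.
#' @param seed base random seed for the cohort.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_subjects = 20,
                       duration_s = 7200,
                       fs_eeg = 256, fs_ecg = 256,
                       so_rate = 20, so_amp_mean = 160, so_amp_sd = 25,
                       so_freq = 0.8, so_rhythm_amp = 20, so_trough_frac = 0.57,
                       spindle_rate = 1.5, spindle_freq = 13, spindle_amp = 25,
                       spindle_prob_base = 0.15, spindle_prob_gain = 0.30,
                       background_slope = 1,
                       hr_mean = 60, lf_freq = 0.1, hf_freq = 0.25,
                       lf_amp = 3, hf_amp = 2,
                       tone_interval_min = 15, tone_interval_max = 30,
                       evoked_base_amp = 170,
                       evoked_gain_so = 20, evoked_gain_lf = 10,
                       evoked_gain_hf = 10,
                       preferred_phase_so = 75, preferred_phase_lf = 60,
                       preferred_phase_hf = -120,
                       evoked_latency_s = 0.22,
                       evoked_echo_frac = 0.5,
                       hr_resp_amp = 5, hr_resp_phase = 45,
                       noise_sd = 12,
                       arousal_rate_per_h = 5, artifact_rate_per_h = 2,
                       seed = 1L) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk_pos <- function(field) {
    if (!is.numeric(cfg[[field]]) || length(cfg[[field]]) != 1 ||
        !is.finite(cfg[[field]]) || cfg[[field]] <= 0) {
      stopf("invalid configuration: '%s' must be a positive number", field)
    }
  }
  chk_nonneg <- function(field) {
    if (!is.numeric(cfg[[field]]) || length(cfg[[field]]) != 1 ||
        !is.finite(cfg[[field]]) || cfg[[field]] < 0) {
      stopf("invalid configuration: '%s' must be non-negative", field)
    }
  }
  for (f in c("n_subjects", "duration_s", "fs_eeg", "fs_ecg", "so_freq",
              "spindle_freq", "hr_mean", "lf_freq", "hf_freq",
              "tone_interval_min", "tone_interval_max", "so_amp_mean")) chk_pos(f)
  # rates, gains and noise may legitimately be zero (ablation configurations)
  for (f in c("so_rate", "spindle_rate", "so_rhythm_amp", "spindle_amp",
              "lf_amp", "hf_amp", "evoked_base_amp", "evoked_gain_so",
              "evoked_gain_lf", "evoked_gain_hf", "noise_sd", "so_amp_sd",
              "arousal_rate_per_h", "artifact_rate_per_h",
              "spindle_prob_base", "spindle_prob_gain", "hr_resp_amp")) chk_nonneg(f)
  if (!(cfg$evoked_echo_frac >= 0 && cfg$evoked_echo_frac < 1)) {
    stopf("invalid configuration: 'evoked_echo_frac' must lie in [0, 1)")
  }
  if (cfg$hr_resp_phase < -180 || cfg$hr_resp_phase >= 180) {
    stopf("invalid configuration: 'hr_resp_phase' must lie in [-180, 180)")
  }
  if (!(cfg$tone_interval_min < cfg$tone_interval_max)) {
    stopf("invalid configuration: 'tone_interval_min' must be < 'tone_interval_max'")
  }
  for (f in c("preferred_phase_so", "preferred_phase_lf", "preferred_phase_hf")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < -180 || v >= 180) {
      stopf("invalid configuration: '%s' must lie in [-180, 180)", f)
    }
  }
  if (cfg$spindle_freq < 11 || cfg$spindle_freq > 16) {
    stopf("invalid configuration: 'spindle_freq' must lie in [11, 16] Hz")
  }
  if (!(cfg$lf_freq >= 0.04 && cfg$lf_freq <= 0.15)) {
    stopf("invalid configuration: 'lf_freq' must lie in the LF band [0.04, 0.15] Hz")
  }
  if (!(cfg$hf_freq >= 0.15 && cfg$hf_freq <= 0.4)) {
    stopf("invalid configuration: 'hf_freq' must lie in the HF band [0.15, 0.4] Hz")
  }
  if (!(cfg$so_trough_frac > 0 && cfg$so_trough_frac < 1)) {
    stopf("invalid configuration: 'so_trough_frac' must lie in (0, 1)")
  }
  invisible(cfg)
}

#' Configuration of a zero-effect (null) cohort
#'
#' Returns `config` with every tone-evoked effect removed: zero base
#' amplitude, zero cosine gains and zero evoked-spindle coupling. Tones
#' are still delivered, so STIM trials are tones coincidentally followed
#' by spontaneous slow oscillations -- the same construction as UNSTIM
#' windows -- which makes STIM and UNSTIM exchangeable.
#'
#' @param config a [sim_config()].
#' @return a modified `sim_config`.
#' @export
null_effect_config <- function(config) {
  config$evoked_base_amp <- 0
  config$evoked_gain_so <- 0
  config$evoked_gain_lf <- 0
  config$evoked_gain_hf <- 0
  config$spindle_prob_gain <- 0
  config$hr_resp_amp <- 0
  config
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_subjects, "subject(s),",
      x$duration_s, "s at", x$fs_eeg, "Hz EEG /", x$fs_ecg, "Hz ECG\n")
  cat("  evoked law: base", x$evoked_base_amp, "uV; gains (so,lf,hf) = (",
      x$evoked_gain_so, ",", x$evoked_gain_lf, ",", x$evoked_gain_hf,
      ") uV at phases (", x$preferred_phase_so, ",", x$preferred_phase_lf,
      ",", x$preferred_phase_hf, ") deg\n")
  invisible(x)
}

#' Write / read a simulation configuration as YAML
#' @param config a [sim_config()].
#' @param path file path.
#' @return `read_sim_config` returns a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(sim_config, cfg)
}
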