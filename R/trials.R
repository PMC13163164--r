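# Shared inclusion rule: the +/- half_window_s around the onset must lie
# inside the recording, wholly within N2/N3 epochs, contain no artifact
# sample and overlap no arousal.
window_is_clean <- function(onset_s, duration_s, hypnogram, artifact_mask, fs,
                            arousals, half_window_s = 10) {
  a <- onset_s - half_window_s
  b <- onset_s + half_window_s
  if (a < 0 || b > duration_s) return(FALSE)
  epochs <- (floor(a / 30) + 1L):(floor((b - 1e-9) / 30) + 1L)
  if (!all(hypnogram[epochs] %in% c("N2", "N3"))) return(FALSE)
  ia <- max(1L, floor(a * fs) + 1L)
  ib <- min(length(artifact_mask), ceiling(b * fs))
  if (any(artifact_mask[ia:ib])) return(FALSE)
  if (nrow(arousals) > 0 &&
      any(arousals$start_s < b & arousals$end_s > a)) return(FALSE)
  TRUE
}

#' Select stimulated (STIM) tone trials
#'
#' Keeps tones whose onset epoch is N2 or N3 and whose +/-10 s window is
#' artifact-free, arousal-free and wholly within N2/N3.
#'
#' @param tones_s tone onsets (s).
#' @param hypnogram stages per 30-s epoch.
#' @param artifact_mask per-EEG-sample logical mask.
#' @param fs EEG sampling rate (Hz).
#' @param arousals data.frame with `start_s`, `end_s`.
#' @param duration_s recording length (s).
#' @param half_window_s window half-length (default 10 s).
#' @return data.frame of candidate trials: `onset_s`, `is_stim`.
#' @export
select_stim_tones <- function(tones_s, hypnogram, artifact_mask, fs, arousals,
                              duration_s, half_window_s = 10) {
  keep <- vapply(tones_s, function(t0) {
    hypnogram[epoch_of(t0)] %in% c("N2", "N3") &&
      window_is_clean(t0, duration_s, hypnogram, artifact_mask, fs, arousals,
                      half_window_s)
  }, logical(1))
  data.frame(onset_s = tones_s[keep],
             is_stim = rep(TRUE, sum(keep)))
}

#' Find unstimulated (UNSTIM) comparison windows
#'
#' Identifies maximal tone-free intervals of at least `min_gap_s` seconds
#' and uses each interval's midpoint as a hypothetical tone onset, subject
#' to the same stage/artifact/arousal criteria as STIM trials. One UNSTIM
#' window is produced per qualifying interval. The response window may not
#' extend beyond the tone-free interval; with a centred midpoint this is
#' guaranteed by the minimum gap.
#'
#' @inheritParams select_stim_tones
#' @param min_gap_s minimum tone-free interval length (default 20 s).
#' @return data.frame of candidate trials: `onset_s`, `is_stim = FALSE`.
#' @export
find_unstim_windows <- function(tones_s, hypnogram, artifact_mask, fs, arousals,
                                duration_s, min_gap_s = 20, half_window_s = 10) {
  bounds <- sort(c(0, tones_s, duration_s))
  lo <- bounds[-length(bounds)]
  hi <- bounds[-1]
  ok_gap <- (hi - lo) >= min_gap_s
  mids <- (lo[ok_gap] + hi[ok_gap]) / 2
  keep <- vapply(mids, function(t0) {
    hypnogram[epoch_of(t0)] %in% c("N2", "N3") &&
      window_is_clean(t0, duration_s, hypnogram, artifact_mask, fs, arousals,
                      half_window_s)
  }, logical(1))
  data.frame(onset_s = mids[keep], is_stim = rep(FALSE, sum(keep)))
}

#' Attach the evoked (or spontaneous) slow oscillation to trials
#'
#' A trial is retained when the first detected slow oscillation whose
#' trough falls in `(onset, onset + max_latency_s]` exists; that event is
#' attached as the trial's response oscillation. The rule applies
#' identically to STIM (tone-evoked) and UNSTIM (spontaneous) trials.
#'
#' @param trials data.frame with `onset_s` (from [select_stim_tones()] /
#'   [find_unstim_windows()]).
#' @param so_events slow-oscillation table from
#'   [detect_slow_oscillations()].
#' @param max_latency_s maximum trough latency (default 2.5 s).
#' @return `trials` with `so_trough_s`, `so_trough_uv`, `so_peak_uv`,
#'   `so_p2p_uv` columns, retaining only rows with an attached event.
#' @export
require_evoked_so <- function(trials, so_events, max_latency_s = 2.5) {
  if (nrow(trials) == 0 || nrow(so_events) == 0) {
    return(cbind(trials[integer(0), , drop = FALSE],
                 data.frame(so_trough_s = numeric(0), so_trough_uv = numeric(0),
                            so_peak_uv = numeric(0), so_p2p_uv = numeric(0))))
  }
  ord <- order(so_events$trough_s)
  tr <- so_events$trough_s[ord]
  pick <- vapply(trials$onset_s, function(t0) {
    i <- findInterval(t0, tr) + 1L          # first trough strictly after onset
    if (i <= length(tr) && tr[i] <= t0 + max_latency_s) ord[i] else NA_integer_
  }, integer(1))
  keep <- !is.na(pick)
  out <- trials[keep, , drop = FALSE]
  ev <- so_events[pick[keep], , drop = FALSE]
  out$so_trough_s <- ev$trough_s
  out$so_trough_uv <- ev$trough_uv
  out$so_peak_uv <- ev$peak_uv
  out$so_p2p_uv <- ev$p2p_uv
  rownames(out) <- NULL
  out
}

#' Quantify per-trial responses
#'
#' Adds the response metrics to retained trials: the attached slow
#' oscillation's peak-to-peak amplitude (already present), normalized SWA
#' over `[onset, onset + 8]` s, the stimulus-dependent-spindle flag
#' (a spindle initiating after the SO trough and before the window end),
#' and the heart-rate peak-to-peak response over `[onset, onset + 10]` s.
#'
#' @param trials retained trials from [require_evoked_so()].
#' @param broadband broadband EEG (for SWA spectra).
#' @param fs EEG sampling rate.
#' @param spindles spindle table from [detect_spindles()].
#' @param hr an `hr_series` (may be NULL: HR responses set to NA).
#' @param swa_window_s SWA window length (default 8 s).
#' @param hr_window_s HR response window length (default 10 s).
#' @param norm_constant optional precomputed PSD normalization constant;
#'   when NULL it is computed from this subject's STIM trials.
#' @return `trials` with `swa_norm`, `spindle_flag`, `hr_p2p_bpm` added,
#'   plus attribute `"norm_constant"`.
#' @export
compute_trial_responses <- function(trials, broadband, fs, spindles, hr = NULL,
                                    swa_window_s = 8, hr_window_s = 10,
                                    norm_constant = NULL) {
  n <- nrow(trials)
  if (n == 0) {
    trials$swa_norm <- numeric(0)
    trials$spindle_flag <- logical(0)
    trials$hr_p2p_bpm <- numeric(0)
    return(trials)
  }
  windows <- cbind(trials$onset_s, trials$onset_s + swa_window_s)
  stim_idx <- which(trials$is_stim)
  if (is.null(norm_constant)) {
    if (length(stim_idx) == 0) stim_idx <- seq_len(n)
    psd <- compute_normalized_psd(broadband, fs, windows, stim_idx)
  } else {
    psd <- compute_normalized_psd(broadband, fs, windows, seq_len(n))
    psd$swa <- psd$swa * psd$norm_constant / norm_constant
    psd$power <- psd$power * psd$norm_constant / norm_constant
    psd$norm_constant <- norm_constant
  }
  trials$swa_norm <- psd$swa
  trials$spindle_flag <- vapply(seq_len(n), function(i) {
    classify_stim_dependent_spindles(spindles, trials$so_trough_s[i],
                                     trials$onset_s[i] + hr_window_s)
  }, logical(1))
  if (is.null(hr)) {
    trials$hr_p2p_bpm <- NA_real_
  } else {
    trials$hr_p2p_bpm <- vapply(seq_len(n), function(i) {
      sel <- hr$t_s >= trials$onset_s[i] &
        hr$t_s <= trials$onset_s[i] + hr_window_s
      if (!any(sel)) return(NA_real_)
      diff(range(hr$hr_bpm[sel]))
    }, numeric(1))
  }
  attr(trials, "norm_constant") <- psd$norm_constant
  attr(trials, "psd_power") <- psd$power
  attr(trials, "psd_freq") <- psd$freq
  trials
}
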