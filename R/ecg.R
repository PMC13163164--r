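#' Detect R-peaks on a band-passed ECG
#'
#' Squared-derivative energy detector: the first difference of the
#' filtered ECG is squared, smoothed over 60 ms, and thresholded at a
#' fraction of a high quantile of the energy; within each supra-threshold
#' region the R-peak is placed at the absolute maximum of the ECG, with a
#' 250 ms refractory period and parabolic sub-sample refinement of the
#' peak time.
#'
#' @param ecg ECG signal (mV), already band-passed 0.5-35 Hz.
#' @param fs sampling rate (Hz).
#' @param refractory_s minimum peak separation (default 0.25 s).
#' @return list of class `rpeak_series`: `peak_times_s`, `rr_s`
#'   (successive differences), `fs`.
#' @export
detect_r_peaks <- function(ecg, fs, refractory_s = 0.25) {
  n <- length(ecg)
  if (n < fs) stopf("ECG shorter than one second")
  d <- c(0, diff(ecg)) * fs
  e <- moving_average(d^2, round(0.06 * fs))
  if (max(e) <= 0) {
    warnf("flat ECG signal: no R-peaks detected")
    return(structure(list(peak_times_s = numeric(0), rr_s = numeric(0), fs = fs),
                     class = "rpeak_series"))
  }
  thr <- 0.2 * stats::quantile(e, 0.99, names = FALSE)
  runs <- true_runs(e > thr)
  refr <- refractory_s
  peaks <- numeric(0)
  last <- -Inf
  for (i in seq_len(nrow(runs))) {
    idx <- runs$start[i]:runs$end[i]
    p <- idx[which.max(abs(ecg[idx]))]
    # parabolic refinement around the sample peak
    tp <- (p - 1) / fs
    if (p > 1 && p < n) {
      y1 <- ecg[p - 1]; y2 <- ecg[p]; y3 <- ecg[p + 1]
      den <- y1 - 2 * y2 + y3
      if (abs(den) > 1e-12) {
        delta <- 0.5 * (y1 - y3) / den
        if (abs(delta) <= 0.5) tp <- tp + delta / fs
      }
    }
    if (tp - last < refr) {
      # keep the larger of the two competing peaks
      if (length(peaks) > 0 && abs(ecg[p]) > abs(ecg[round(last * fs) + 1])) {
        peaks[length(peaks)] <- tp
        last <- tp
      }
      next
    }
    peaks <- c(peaks, tp)
    last <- tp
  }
  structure(list(peak_times_s = peaks, rr_s = diff(peaks), fs = fs),
            class = "rpeak_series")
}

#' Instantaneous heart rate on a uniform 10 Hz grid
#'
#' Beatwise HR (60/RR, bpm) is anchored at each RR interval's midpoint
#' (an interval's 60/RR is its mean rate, which a slowly varying
#' modulation attains mid-interval; end-beat anchoring would lag the true
#' rate by half an interval and bias fast HF phases). Intervals whose RR
#' deviates from the whole-recording mean by more than 10 standard
#' deviations (either tail) or fall outside plausible bounds (0.25-3 s)
#' are excluded before interpolation. The retained beatwise values are
#' cubic-spline interpolated onto a 0.1-s grid spanning the retained
#' beats.
#'
#' @param rpeaks an `rpeak_series` from [detect_r_peaks()].
#' @param grid_hz interpolation rate (default 10 Hz).
#' @param rr_z_limit RR outlier z-score limit (default 10).
#' @return list of class `hr_series`: `t_s`, `hr_bpm`, plus empty `lf`/`hf`
#'   slots filled by [decompose_hr()].
#' @export
derive_instantaneous_hr <- function(rpeaks, grid_hz = 10, rr_z_limit = 10) {
  rr <- rpeaks$rr_s
  if (length(rr) < 10) stopf("need at least 10 beats to derive instantaneous HR")
  t_anchor <- rpeaks$peak_times_s[-length(rpeaks$peak_times_s)] + rr / 2
  valid <- rr > 0.25 & rr < 3
  mu <- mean(rr); s <- stats::sd(rr)
  if (is.finite(s) && s > 0) valid <- valid & abs(rr - mu) / s <= rr_z_limit
  if (sum(valid) < 10) stopf("fewer than 10 valid beats after RR outlier exclusion")
  hr_beat <- 60 / rr[valid]
  t_beat <- t_anchor[valid]
  step <- 1 / grid_hz
  t_grid <- seq(ceiling(t_beat[1] / step) * step,
                floor(t_beat[length(t_beat)] / step) * step, by = step)
  hr <- stats::spline(t_beat, hr_beat, xout = t_grid, method = "fmm")$y
  structure(list(t_s = t_grid, hr_bpm = hr, lf = NULL, hf = NULL,
                 fs = grid_hz), class = "hr_series")
}

#' Decompose instantaneous HR into LF and HF components
#'
#' Fourth-order zero-phase Butterworth band-passes at 0.04-0.15 Hz (LF)
#' and 0.15-0.4 Hz (HF) applied to the 10 Hz instantaneous HR. The first
#' and last `edge_s` seconds are flagged unreliable (`reliable` mask) and
#' should be excluded from phase queries near record boundaries.
#'
#' @param hr an `hr_series` from [derive_instantaneous_hr()].
#' @param lf_band,hf_band band edges in Hz.
#' @param edge_s unreliable edge span (default 30 s).
#' @return the `hr_series` with `lf`, `hf` and `reliable` filled in.
#' @export
decompose_hr <- function(hr, lf_band = c(0.04, 0.15), hf_band = c(0.15, 0.4),
                         edge_s = 30) {
  if (length(hr$t_s) < 100 * hr$fs) {
    stopf("HR record shorter than 100 s; LF decomposition undefined")
  }
  x <- hr$hr_bpm - mean(hr$hr_bpm)
  hr$lf <- zero_phase_bandpass(x, lf_band[1], lf_band[2], fs = hr$fs)
  hr$hf <- zero_phase_bandpass(x, hf_band[1], hf_band[2], fs = hr$fs)
  n <- length(hr$t_s)
  edge <- round(edge_s * hr$fs)
  hr$reliable <- rep(TRUE, n)
  if (edge > 0 && n > 2 * edge) {
    hr$reliable[c(seq_len(edge), (n - edge + 1L):n)] <- FALSE
  }
  hr
}
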