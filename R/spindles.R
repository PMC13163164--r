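# Morlet wavelet power of a segment at one centre frequency.
# width = number of cycles of the Gaussian envelope (standard complex
# Morlet with sigma_t = width / (2 * pi * f)).
morlet_power <- function(x, fs, freq, width = 6) {
  sigma_t <- width / (2 * pi * freq)
  half <- ceiling(3.5 * sigma_t * fs)
  tt <- (-half:half) / fs
  w <- exp(2i * pi * freq * tt) * exp(-tt^2 / (2 * sigma_t^2))
  w <- w / sum(Mod(w))
  nx <- length(x)
  nw <- length(w)
  # linear convolution via FFT, centred
  nfft <- stats::nextn(nx + nw - 1L)
  conv <- stats::fft(stats::fft(c(x, numeric(nfft - nx))) *
                       stats::fft(c(w, complex(real = numeric(nfft - nw)))),
                     inverse = TRUE) / nfft
  centre <- conv[((nw - 1L) %/% 2L) + seq_len(nx)]
  Mod(centre)^2
}

# Event-averaged Morlet spectrum over 10-20 Hz (0.5 Hz steps) and the
# unimodality check: exactly one local maximum inside 11-16 Hz and all
# power above 16 Hz strictly below that maximum.
spindle_spectrum_check <- function(broadband, fs, start_idx, end_idx,
                                   freqs = seq(10, 20, by = 0.5), width = 6) {
  pad <- round(0.5 * fs)
  lo <- max(1L, start_idx - pad)
  hi <- min(length(broadband), end_idx + pad)
  seg <- broadband[lo:hi]
  ev <- (start_idx - lo + 1L):(end_idx - lo + 1L)
  spec <- vapply(freqs, function(f) mean(morlet_power(seg, fs, f, width)[ev]),
                 numeric(1))
  in_band <- freqs >= 11 & freqs <= 16
  above <- freqs > 16
  interior <- which(in_band)
  is_locmax <- vapply(interior, function(i) {
    spec[i] > spec[i - 1L] && spec[i] > spec[i + 1L]
  }, logical(1))
  n_max <- sum(is_locmax)
  if (n_max != 1L) return(list(ok = FALSE, peak_freq = NA_real_))
  pk <- interior[is_locmax][1]
  ok <- all(spec[above] < spec[pk])
  list(ok = ok, peak_freq = freqs[pk])
}

#' Detect sleep spindles
#'
#' RMS envelope of the 11-16 Hz signal (0.2-s sliding window) thresholded
#' at the 88.86th percentile of envelope values over artifact-free N2/N3
#' samples. A maximal supra-threshold interval becomes a spindle when it
#' lies wholly in artifact-free N2/N3, lasts 0.3-3 s, contains at least
#' five full oscillations (counted between successive positive-going zero
#' crossings of the band signal), and its event-averaged Morlet spectrum
#' has exactly one local maximum within 11-16 Hz with all 16-20 Hz power
#' strictly below it.
#'
#' @param spindle_band 11-16 Hz filtered EEG (microvolts).
#' @param broadband broadband EEG used for the wavelet check.
#' @param fs sampling rate (Hz).
#' @param n2n3_mask logical, TRUE during N2/N3 sleep.
#' @param artifact_mask logical, TRUE where artifact (optional).
#' @param percentile envelope threshold percentile (default 88.86).
#' @param threshold absolute envelope threshold overriding the percentile
#'   (for applying a calibrated threshold to new data).
#' @param rms_window_s RMS window (default 0.2 s).
#' @return data.frame: `start_s`, `end_s`, `duration_s`, `n_oscillations`,
#'   `peak_freq_hz`, `rms_peak`.
#' @export
detect_spindles <- function(spindle_band, broadband, fs, n2n3_mask,
                            artifact_mask = NULL, percentile = 88.86,
                            threshold = NULL, rms_window_s = 0.2) {
  n <- length(spindle_band)
  if (is.null(artifact_mask)) artifact_mask <- rep(FALSE, n)
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_s = numeric(0), n_oscillations = integer(0),
                      peak_freq_hz = numeric(0), rms_peak = numeric(0))
  env <- sqrt(moving_average(spindle_band^2, round(rms_window_s * fs)))
  ref <- n2n3_mask & !artifact_mask
  if (is.null(threshold)) {
    if (!any(ref)) stopf("spindle threshold undefined: no artifact-free N2/N3 samples")
    threshold <- stats::quantile(env[ref], percentile / 100, names = FALSE)
  }
  runs <- true_runs(env > threshold)
  if (nrow(runs) == 0) return(empty)
  out <- vector("list", nrow(runs))
  k <- 0L
  # the RMS window smears the envelope outward by half a window on each
  # side; trim the supra-threshold run by that known support so event
  # bounds and durations refer to the underlying burst
  trim <- round(rms_window_s * fs) %/% 2L
  for (i in seq_len(nrow(runs))) {
    s <- runs$start[i] + trim; e <- runs$end[i] - trim
    if (e <= s) next
    dur <- (e - s + 1L) / fs
    if (dur < 0.3 || dur > 3) next
    if (!all(ref[s:e])) next
    seg <- spindle_band[s:e]
    up <- sum(seg[-length(seg)] < 0 & seg[-1] >= 0)
    n_osc <- max(0L, up - 1L)
    if (n_osc < 5L) next
    chk <- spindle_spectrum_check(broadband, fs, s, e)
    if (!chk$ok) next
    k <- k + 1L
    out[[k]] <- data.frame(start_s = (s - 1L) / fs, end_s = (e - 1L) / fs,
                           duration_s = dur, n_oscillations = n_osc,
                           peak_freq_hz = chk$peak_freq,
                           rms_peak = max(env[s:e]))
  }
  if (k == 0L) return(empty)
  do.call(rbind, out[seq_len(k)])
}

#' Stimulus-dependent spindle classification
#'
#' A trial carries a stimulus-dependent spindle when at least one detected
#' spindle starts strictly after the evoked (or spontaneous) slow
#' oscillation's trough and no later than the end of the trial window.
#' The spindle likelihood of a condition is the proportion of trials for
#' which this is true.
#'
#' @param spindles spindle table from [detect_spindles()].
#' @param trough_s trough time of the trial's slow oscillation (s).
#' @param window_end_s end of the trial window (s).
#' @return logical flag.
#' @export
classify_stim_dependent_spindles <- function(spindles, trough_s, window_end_s) {
  if (is.null(spindles) || nrow(spindles) == 0) return(FALSE)
  any(spindles$start_s > trough_s & spindles$start_s <= window_end_s)
}
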