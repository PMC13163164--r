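#' Welch power spectral density
#'
#' Hann-windowed, overlapping-segment averaged periodogram. Power is
#' density-scaled (signal units squared per Hz) with the window's power
#' normalisation, so white noise of variance `s^2` has a flat PSD of
#' `s^2 / (fs/2)`.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param seg_s segment length in seconds (default 4).
#' @param overlap fractional overlap between segments (default 0.5).
#' @return list with `freq` (Hz) and `power`.
#' @export
welch_psd <- function(x, fs, seg_s = 4, overlap = 0.5) {
  nper <- round(seg_s * fs)
  if (length(x) < nper) stopf("signal shorter than one Welch segment (%g s)", seg_s)
  step <- max(1L, round(nper * (1 - overlap)))
  starts <- seq(1L, length(x) - nper + 1L, by = step)
  w <- hann_window(nper)
  u <- sum(w^2)                       # window power normalisation
  acc <- numeric(nper %/% 2 + 1L)
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- Mod(stats::fft(seg)[seq_along(acc)])^2
    acc <- acc + sp
  }
  pxx <- acc / (length(starts) * u * fs)
  # one-sided: double everything except DC and Nyquist
  if (length(pxx) > 2) pxx[2:(length(pxx) - 1L)] <- 2 * pxx[2:(length(pxx) - 1L)]
  list(freq = (seq_along(pxx) - 1L) * fs / nper, power = pxx)
}

#' Normalized per-window power spectra and slow-wave activity
#'
#' Computes a Welch PSD (4-s Hann segments, 50% overlap) for each analysis
#' window, linearly interpolates each spectrum onto a 0.1 Hz grid
#' (0-20 Hz), and normalizes every spectrum by the subject's mean total
#' power over 0-20 Hz across the stimulated windows ("total" being the
#' mean over grid points). Slow-wave activity (SWA) is the mean normalized
#' power over grid points in [0.5, 4] Hz.
#'
#' @param broadband broadband EEG (microvolts).
#' @param fs sampling rate (Hz).
#' @param windows_s two-column matrix or data.frame of window start/end
#'   times (s); each window must be at least 8 s long.
#' @param stim_idx indices of `windows_s` rows that are stimulated windows
#'   (the normalization reference). Defaults to all windows.
#' @param grid_hz frequency grid (default `seq(0, 20, 0.1)`).
#' @return list with `freq` (grid), `power` (windows x freqs matrix of
#'   normalized PSDs), `swa` (per window), `norm_constant`.
#' @export
compute_normalized_psd <- function(broadband, fs, windows_s,
                                   stim_idx = NULL,
                                   grid_hz = seq(0, 20, by = 0.1)) {
  windows_s <- as.matrix(windows_s)
  if (ncol(windows_s) != 2) stopf("windows_s must have two columns (start, end)")
  if (any(windows_s[, 2] - windows_s[, 1] < 8 - 1e-9)) {
    stopf("each PSD window must be at least 8 s long")
  }
  if (is.null(stim_idx)) stim_idx <- seq_len(nrow(windows_s))
  n <- length(broadband)
  pw <- matrix(NA_real_, nrow(windows_s), length(grid_hz))
  for (i in seq_len(nrow(windows_s))) {
    a <- max(1L, round(windows_s[i, 1] * fs) + 1L)
    b <- min(n, round(windows_s[i, 2] * fs))
    if (b - a + 1L < round(4 * fs)) stopf("window %d shorter than one Welch segment", i)
    psd <- welch_psd(broadband[a:b], fs)
    pw[i, ] <- stats::approx(psd$freq, psd$power, xout = grid_hz, rule = 2)$y
  }
  totals <- rowMeans(pw)
  norm_constant <- mean(totals[stim_idx])
  if (!is.finite(norm_constant) || norm_constant <= 0) {
    stopf("degenerate normalization constant")
  }
  pw <- pw / norm_constant
  swa_cols <- grid_hz >= 0.5 & grid_hz <= 4
  list(freq = grid_hz, power = pw, swa = rowMeans(pw[, swa_cols, drop = FALSE]),
       norm_constant = norm_constant)
}
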