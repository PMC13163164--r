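#' Analytic signal via the discrete Hilbert transform
#'
#' FFT implementation: positive frequencies doubled, negative zeroed.
#' @param x real-valued signal.
#' @return complex analytic signal of the same length.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of a narrowband signal
#'
#' Computes the Hilbert analytic-signal angle and applies the +90 degree
#' quadrature correction so that -90 deg falls at signal troughs, 0 deg at
#' negative-to-positive zero crossings and +90 deg at peaks. Edge
#' transients of the Hilbert transform are suppressed by reflection
#' padding (default 10 s) before the transform; the padding is discarded
#' afterwards.
#'
#' @param x narrowband, zero-mean signal (e.g. the 0.5-4 Hz EEG or an HR
#'   band component).
#' @param fs sampling rate (Hz).
#' @param pad_s reflection padding in seconds.
#' @return numeric vector of phases in degrees, in `[-180, 180)`.
#' @export
instantaneous_phase <- function(x, fs, pad_s = 10) {
  if (all(x == 0)) stopf("phase undefined for an all-zero signal")
  x <- x - mean(x)
  n <- length(x)
  pad <- min(n - 1L, round(pad_s * fs))
  xp <- if (pad > 0) c(rev(x[seq_len(pad) + 1L]), x, rev(x[n - seq_len(pad)])) else x
  a <- analytic_signal(xp)
  ph <- Arg(a[(pad + 1L):(pad + n)]) * 180 / pi + 90
  wrap_deg(ph)
}

#' Build a phase series (grid + phase)
#'
#' Convenience wrapper pairing a time grid with corrected Hilbert phases.
#' @param x narrowband signal.
#' @param fs sampling rate (Hz).
#' @param t0 time of the first sample (s).
#' @param source label, one of `"EEG_SO"`, `"HR_LF"`, `"HR_HF"`.
#' @return list with `t_s`, `phase_deg`, `source`, `fs`.
#' @export
phase_series <- function(x, fs, t0 = 0, source = "EEG_SO") {
  structure(list(
    t_s = t0 + (seq_along(x) - 1L) / fs,
    phase_deg = instantaneous_phase(x, fs),
    source = source, fs = fs
  ), class = "phase_series")
}

#' Look up phases at event times
#'
#' Nearest-sample lookup on the series' grid. Events outside the grid span
#' (beyond half a sample step) yield NA with a warning.
#'
#' @param series a [phase_series()] object.
#' @param event_times_s numeric event times (s).
#' @return phases in degrees, NA for out-of-span events.
#' @export
phase_at <- function(series, event_times_s) {
  t <- series$t_s
  step <- 1 / series$fs
  idx <- round((event_times_s - t[1]) / step) + 1L
  out <- rep(NA_real_, length(event_times_s))
  ok <- idx >= 1L & idx <= length(t)
  out[ok] <- series$phase_deg[idx[ok]]
  if (any(!ok)) warnf("%d event(s) outside the phase series span; returned NA", sum(!ok))
  out
}

#' Overlapping circular phase-bin grid
#'
#' 24 bins of width 60 degrees, stepped by 15 degrees around the circle.
#' Each bin is the left-open interval `(left, left + 60]` wrapped
#' circularly, so that every phase belongs to exactly four bins.
#'
#' @param width_deg bin width (default 60).
#' @param step_deg bin step (default 15).
#' @return data.frame with `bin`, `left_deg`, `center_deg`.
#' @export
phase_bin_grid <- function(width_deg = 60, step_deg = 15) {
  lefts <- seq(-180, 180 - step_deg, by = step_deg)
  data.frame(bin = seq_along(lefts),
             left_deg = lefts,
             center_deg = wrap_deg(lefts + width_deg / 2),
             width_deg = width_deg)
}

#' Bins containing a phase
#'
#' @param phi phase in degrees, in `[-180, 180)`; vectorised.
#' @param grid a [phase_bin_grid()].
#' @return for scalar input, integer bin indices; for vector input, a list.
#' @export
bin_membership <- function(phi, grid = phase_bin_grid()) {
  one <- function(p) {
    d <- (p - grid$left_deg) %% 360
    grid$bin[d > 0 & d <= grid$width_deg]
  }
  if (length(phi) == 1L) one(phi) else lapply(phi, one)
}

# Logical membership matrix: rows = phases, cols = bins.
bin_membership_matrix <- function(phi, grid = phase_bin_grid()) {
  d <- outer(phi, grid$left_deg, function(p, l) (p - l) %% 360)
  d > 0 & d <= grid$width_deg[1]
}

#' Binary upstate/downstate classification
#'
#' Downstate is `[-180, 0)`, upstate `[0, 180)`; 0 degrees (the
#' negative-to-positive zero crossing) belongs to the upstate.
#'
#' @param phi phase in degrees; vectorised.
#' @return character vector of `"U"` / `"D"`.
#' @export
classify_state <- function(phi) {
  ifelse(wrap_deg(phi) >= 0, "U", "D")
}

#' The eight analysed phase-locking conditions
#'
#' Condition labels give the required state of (EEG SO, HR-LF, HR-HF) in
#' order; `U` = upstate, `D` = downstate, `-` = no phase-locking to that
#' signal. The analysed set targets the optimal states: SO upstate, HR-LF
#' upstate, HR-HF downstate.
#'
#' @return data.frame with `label`, `so`, `lf`, `hf` columns (each
#'   `"U"`, `"D"` or `"-"`).
#' @export
condition_specs <- function() {
  specs <- rbind(
    c("---", "-", "-", "-"),
    c("U--", "U", "-", "-"),
    c("-U-", "-", "U", "-"),
    c("--D", "-", "-", "D"),
    c("UU-", "U", "U", "-"),
    c("U-D", "U", "-", "D"),
    c("-UD", "-", "U", "D"),
    c("UUD", "U", "U", "D")
  )
  data.frame(label = specs[, 1], so = specs[, 2], lf = specs[, 3],
             hf = specs[, 4], stringsAsFactors = FALSE)
}

#' Assign phase-locking conditions to tone states
#'
#' A tone matches a condition when every constrained slot equals the tone's
#' binary state; unconstrained slots (`-`) always match, so every tone
#' matches the open-loop condition `---`.
#'
#' @param state_so,state_lf,state_hf per-tone `"U"`/`"D"` states
#'   (vectorised; NA states fail every constrained slot).
#' @param specs conditions, as from [condition_specs()].
#' @return logical matrix, tones x conditions, with condition labels as
#'   column names.
#' @export
assign_conditions <- function(state_so, state_lf, state_hf,
                              specs = condition_specs()) {
  n <- length(state_so)
  m <- matrix(FALSE, n, nrow(specs), dimnames = list(NULL, specs$label))
  for (j in seq_len(nrow(specs))) {
    ok <- rep(TRUE, n)
    if (specs$so[j] != "-") ok <- ok & !is.na(state_so) & state_so == specs$so[j]
    if (specs$lf[j] != "-") ok <- ok & !is.na(state_lf) & state_lf == specs$lf[j]
    if (specs$hf[j] != "-") ok <- ok & !is.na(state_hf) & state_hf == specs$hf[j]
    m[, j] <- ok
  }
  m
}
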