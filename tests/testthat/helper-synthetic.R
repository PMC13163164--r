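# Shared builders for synthetic test inputs.

circ_diff <- function(a, b) ((a - b + 180) %% 360) - 180

local_tukey <- function(n, alpha = 0.25) {
  x <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  edge <- alpha / 2
  w[x < edge] <- 0.5 * (1 + cos(pi * (2 * x[x < edge] / alpha - 1)))
  w[x > 1 - edge] <- 0.5 * (1 + cos(pi * (2 * (1 - x[x > 1 - edge]) / alpha - 1)))
  w
}

# Tukey-windowed sinusoidal burst, amplitude `amp`, duration `dur_s`.
# Short 5% tapers keep the burst's extent sharply defined.
make_burst <- function(amp, dur_s, freq, fs, alpha = 0.1) {
  n <- round(dur_s * fs)
  amp * sin(2 * pi * freq * (seq_len(n) - 1) / fs) * local_tukey(n, alpha)
}

# A single slow-oscillation-like cycle with exactly the given trough and
# peak voltages, delimited by small positive/negative lobes so that the
# downward zero crossings bracketing it are unambiguous.
make_so_cycle <- function(trough_uv, peak_uv, fs, half_s = 0.5, lobe_uv = 5) {
  half <- function(a, w) a * sin(pi * seq(0, 1, length.out = round(w * fs)))
  c(half(lobe_uv, 0.3), half(trough_uv, half_s), half(peak_uv, half_s),
    half(-lobe_uv, 0.3))
}

# Literal brute-force slow-oscillation oracle: enumerate downward
# zero-crossing segments and apply the amplitude/duration criteria.
brute_force_so <- function(x, fs, trough_max = -80, p2p_min = 140,
                           dur_range = c(0.25, 2.5)) {
  n <- length(x)
  dz <- integer(0)
  for (i in seq_len(n - 1)) if (x[i] > 0 && x[i + 1] <= 0) dz <- c(dz, i)
  out <- NULL
  if (length(dz) < 2) {
    return(data.frame(start_s = numeric(0), trough_uv = numeric(0),
                      peak_uv = numeric(0), duration_s = numeric(0)))
  }
  t_dz <- (dz - 1 + x[dz] / (x[dz] - x[dz + 1])) / fs
  for (i in seq_len(length(dz) - 1)) {
    seg <- x[(dz[i] + 1):dz[i + 1]]
    dur <- t_dz[i + 1] - t_dz[i]
    if (dur < dur_range[1] || dur > dur_range[2]) next
    tr <- min(seg); pk <- max(seg)
    if (tr < trough_max && pk - tr > p2p_min) {
      out <- rbind(out, data.frame(start_s = t_dz[i], trough_uv = tr,
                                   peak_uv = pk, duration_s = dur))
    }
  }
  if (is.null(out)) {
    out <- data.frame(start_s = numeric(0), trough_uv = numeric(0),
                      peak_uv = numeric(0), duration_s = numeric(0))
  }
  out
}

# Smooth random slow-oscillation-band-like trace (for oracle equivalence).
random_so_trace <- function(fs = 64, dur_s = 30, scale = 120) {
  x <- stats::rnorm(dur_s * fs)
  zero_phase_bandpass(x, 0.5, 4, fs) * scale / stats::sd(zero_phase_bandpass(x, 0.5, 4, fs))
}

# Build a record of band-limited noise plus injected 13 Hz bursts, and the
# matching spindle-band / broadband pair the detector expects.
build_spindle_record <- function(n_bursts = 12, amp = 12, noise_sd = 5,
                                 fs = 128, dur_range = c(0.5, 1.5),
                                 gap_s = 20, freq = 13, seed = 5) {
  set.seed(seed)
  total_s <- n_bursts * gap_s + 10
  n <- total_s * fs
  eeg <- rnorm(n, 0, noise_sd)
  starts <- numeric(n_bursts)
  durs <- numeric(n_bursts)
  for (i in seq_len(n_bursts)) {
    durs[i] <- runif(1, dur_range[1], dur_range[2])
    starts[i] <- (i - 1) * gap_s + 3
    b <- make_burst(amp, durs[i], freq, fs)
    i0 <- round(starts[i] * fs) + 1
    eeg[i0:(i0 + length(b) - 1)] <- eeg[i0:(i0 + length(b) - 1)] + b
  }
  list(spindle_band = zero_phase_bandpass(eeg, 11, 16, fs),
       broadband = zero_phase_bandpass(eeg, 0.1, 30, fs),
       n2n3 = rep(TRUE, n), fs = fs, starts = starts, durs = durs)
}
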