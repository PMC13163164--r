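#' Detect slow oscillations on the 0.5-4 Hz signal
#'
#' A candidate is the stretch between two successive downward
#' (positive-to-negative) zero crossings. Within a candidate the trough is
#' the minimum and the peak the maximum. An event is kept when the trough
#' is strictly below -80 microvolts, the peak-to-peak amplitude strictly
#' above 140 microvolts, the duration between the two downward crossings is
#' within [0.25, 2.5] s inclusive, and no sample overlaps the artifact
#' mask. Zero-crossing times are linearly interpolated between samples.
#'
#' @param so_band slow-oscillation band EEG (microvolts).
#' @param fs sampling rate (Hz).
#' @param artifact_mask optional logical mask, TRUE where artifact.
#' @param trough_uv_max trough criterion (default -80, strict `<`).
#' @param p2p_uv_min peak-to-peak criterion (default 140, strict `>`).
#' @param duration_range_s inclusive duration bounds (default 0.25-2.5 s).
#' @return data.frame of events sorted by `start_s`: `start_s`, `end_s`,
#'   `duration_s`, `trough_s`, `trough_uv`, `peak_s`, `peak_uv`, `p2p_uv`.
#' @export
detect_slow_oscillations <- function(so_band, fs, artifact_mask = NULL,
                                     trough_uv_max = -80, p2p_uv_min = 140,
                                     duration_range_s = c(0.25, 2.5)) {
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      duration_s = numeric(0), trough_s = numeric(0),
                      trough_uv = numeric(0), peak_s = numeric(0),
                      peak_uv = numeric(0), p2p_uv = numeric(0))
  n <- length(so_band)
  if (n < 2) return(empty)
  if (is.null(artifact_mask)) artifact_mask <- rep(FALSE, n)
  # downward zero crossings: sample i with x[i] > 0 and x[i+1] <= 0
  dz <- which(so_band[-n] > 0 & so_band[-1] <= 0)
  if (length(dz) < 2) return(empty)
  # sub-sample crossing time by linear interpolation
  frac <- so_band[dz] / (so_band[dz] - so_band[dz + 1L])
  t_dz <- (dz - 1L + frac) / fs
  out <- vector("list", length(dz) - 1L)
  k <- 0L
  for (i in seq_len(length(dz) - 1L)) {
    dur <- t_dz[i + 1L] - t_dz[i]
    if (dur < duration_range_s[1] || dur > duration_range_s[2]) next
    idx <- (dz[i] + 1L):dz[i + 1L]
    if (any(artifact_mask[idx])) next
    seg <- so_band[idx]
    i_min <- which.min(seg)
    i_max <- which.max(seg)
    trough <- seg[i_min]
    peak <- seg[i_max]
    if (!(trough < trough_uv_max)) next
    if (!(peak - trough > p2p_uv_min)) next
    k <- k + 1L
    out[[k]] <- c(t_dz[i], t_dz[i + 1L], dur,
                  (idx[i_min] - 1L) / fs, trough,
                  (idx[i_max] - 1L) / fs, peak, peak - trough)
  }
  if (k == 0L) return(empty)
  m <- do.call(rbind, out[seq_len(k)])
  stats::setNames(as.data.frame(m), names(empty))
}
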