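#' @keywords internal
"_PACKAGE"

# Wrap angles (degrees) to the half-open interval [-180, 180).
wrap_deg <- function(x) {
  ((x + 180) %% 360) - 180
}

# Centered moving average with a rectangular window of k samples.
# Edges are handled by shrinking the window (partial means), so the
# output has no NA values and the same length as the input.
moving_average <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k == 1L) return(x)
  cs <- cumsum(c(0, x))
  n <- length(x)
  half_l <- (k - 1L) %/% 2L
  half_r <- k %/% 2L
  lo <- pmax(seq_len(n) - half_l, 1L)
  hi <- pmin(seq_len(n) + half_r, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Tukey (tapered cosine) window, taper fraction alpha of the total length.
tukey_window <- function(n, alpha = 0.25) {
  if (n == 1L) return(1)
  x <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  edge <- alpha / 2
  lo <- x < edge
  hi <- x > 1 - edge
  w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - x[hi]) / alpha - 1)))
  w
}

hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}

# Index runs of TRUE values; returns a data.frame(start, end) of indices.
true_runs <- function(mask) {
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & !is.na(r$values)
  data.frame(start = starts[keep], end = ends[keep])
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
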