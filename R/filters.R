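# Shared signal-processing primitives: zero-phase IIR filtering, notch,
# decimation, Welch spectral estimation, and deterministic seed derivation.

# Forward-backward filtering with odd-reflection padding: suppresses the
# start/end transients that plain filtfilt leaves when the filter's
# settling time is long relative to the signal (e.g. very low cutoffs).
# The mean is filtered analytically (DC gain), so a constant input yields
# an exactly constant output and filtering is exactly affine-equivariant.
filtfilt_padded <- function(bf, x, pad) {
  n <- length(x)
  m <- mean(x)
  dc2 <- (sum(bf$b) / sum(bf$a))^2  # filtfilt squares the DC gain
  x <- x - m
  pad <- min(n - 1, max(1, round(pad)))
  head_pad <- 2 * x[1] - x[(pad + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
  as.numeric(y[(pad + 1):(pad + n)]) + m * dc2
}

#' Zero-phase Butterworth filter
#'
#' Designs a Butterworth filter and applies it forward-backward
#' (zero-phase), with odd-reflection edge padding sized to the filter's
#' settling time. Cutoffs are in Hz.
#'
#' @param x numeric signal vector.
#' @param fs sampling rate (Hz).
#' @param type one of "low", "high", "pass".
#' @param cutoff scalar cutoff (low/high) or length-2 band edges (pass), Hz.
#' @param order filter order (per section).
#' @return filtered signal, same length as `x`.
#' @export
butter_filtfilt <- function(x, fs, type = c("low", "high", "pass"),
                            cutoff, order = 4) {
  type <- match.arg(type)
  w <- cutoff / (fs / 2)
  if (any(w <= 0) || any(w >= 1)) {
    stop("cutoff must lie strictly inside (0, fs/2)")
  }
  bf <- switch(type,
    low  = signal::butter(order, w, type = "low"),
    high = signal::butter(order, w, type = "high"),
    pass = signal::butter(order, w, type = "pass")
  )
  # settling time grows with order (slowest pole approaches the jw axis):
  # pad ~(1 + order/2) / f seconds
  filtfilt_padded(bf, x, pad = (1 + 0.5 * order) * fs / min(cutoff))
}

#' Zero-phase IIR notch filter
#'
#' Second-order notch (biquad) at `freq` Hz with quality factor `Q`,
#' applied forward-backward.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param freq notch centre frequency (Hz), default 50 (power line).
#' @param Q quality factor (centre frequency / -3 dB bandwidth).
#' @return filtered signal.
#' @export
notch_filter <- function(x, fs, freq = 50, Q = 30) {
  w0 <- 2 * pi * freq / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  filtfilt_padded(signal::Arma(b = b / a[1], a = a / a[1]), x,
                  pad = 3 * fs * Q / freq)
}

# Anti-aliased integer-factor decimation; factors > 8 are split into a
# chain of smaller stages for filter stability. Mean removal plus
# odd-reflection padding suppress the edge transients of the internal
# anti-alias filter.
decimate_by <- function(x, q) {
  stopifnot(q >= 1, q == round(q))
  if (q == 1) return(x)
  n <- length(x)
  stages <- c()
  rem <- q
  for (f in c(8, 7, 6, 5, 4, 3, 2)) {
    while (rem %% f == 0 && rem > 1) {
      stages <- c(stages, f)
      rem <- rem / f
    }
  }
  if (rem != 1) stages <- c(stages, rem)
  m <- mean(x)
  pad <- min(n - 1, 30 * q)
  pad <- pad - pad %% q  # keep the output grid aligned
  y <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)]) - m
  for (f in stages) y <- as.numeric(signal::decimate(y, f, ftype = "iir"))
  drop_n <- pad / q
  y[(drop_n + 1):(length(y) - drop_n)] + m
}

#' Welch power spectral density
#'
#' Averaged modified periodograms with a Hann window and 50% segment
#' overlap. One-sided density in units of `x`^2 / Hz.
#'
#' @param x numeric signal (assumed uniformly sampled, detrended by mean
#'   removal per segment).
#' @param fs sampling rate (Hz).
#' @param seg_len_s segment length in seconds; shrunk to the full signal
#'   length if the signal is shorter.
#' @return data.frame with columns `freq` (Hz) and `psd`.
#' @export
welch_psd <- function(x, fs, seg_len_s = 64) {
  n <- length(x)
  L <- min(n, round(seg_len_s * fs))
  if (L < 8) stop("signal too short for spectral estimation")
  hop <- max(1, floor(L / 2))
  starts <- seq(1, n - L + 1, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))  # Hann
  norm <- fs * sum(w^2)
  nfreq <- floor(L / 2) + 1
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + L - 1)]
    seg <- (seg - mean(seg)) * w
    p <- abs(stats::fft(seg))^2 / norm
    p <- p[seq_len(nfreq)]
    # fold negative frequencies (one-sided density)
    p[2:(nfreq - 1)] <- 2 * p[2:(nfreq - 1)]
    acc <- acc + p
  }
  data.frame(freq = (seq_len(nfreq) - 1) * fs / L, psd = acc / length(starts))
}

#' Integrate a PSD over a frequency band
#'
#' @param psd data.frame from [welch_psd()].
#' @param lo,hi band edges in Hz; bins with `lo <= freq < hi` are summed.
#' @return band power (units of signal^2).
#' @export
band_power <- function(psd, lo, hi) {
  df <- psd$freq[2] - psd$freq[1]
  sel <- psd$freq >= lo & psd$freq < hi
  sum(psd$psd[sel]) * df
}

# Deterministic 32-bit seed derived from a base seed and stream indices.
# Keeps every derived seed in [1, 2^31 - 2] so set.seed() is safe.
derive_seed <- function(seed, ...) {
  v <- c(seed, ...)
  s <- 0
  for (x in v) s <- (s * 69069 + as.numeric(x) + 1) %% 2147483629
  as.integer(s + 1)
}
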