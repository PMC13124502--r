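# Wavelet-packet alpha-band power for EEG asymmetry analysis.
#
# Five-level db4 wavelet-packet decomposition of the 128 Hz signal gives
# 32 terminal nodes of 2 Hz each; the nodes spanning 8-14 Hz (the closest
# dyadic cover of the 8-13 Hz alpha band) are reconstructed and summed.
# Periodic boundary handling makes the transform orthogonal, so the
# analysis/synthesis pair achieves perfect reconstruction.

# Daubechies-4 (8-tap) filter bank.
DB4_DEC_LO <- c(-0.010597401785069032, 0.032883011666885197,
                0.030841381835560764, -0.18703481171909309,
                -0.027983769416859854, 0.63088076792985892,
                0.71484657055291567, 0.23037781330889651)
DB4_DEC_HI <- c(-0.23037781330889651, 0.71484657055291567,
                -0.63088076792985892, -0.027983769416859854,
                0.18703481171909309, 0.030841381835560764,
                -0.032883011666885197, -0.010597401785069032)

# Periodic correlation with filter h followed by dyadic downsampling.
.wp_analysis_step <- function(x, h) {
  n <- length(x)
  hp <- c(h, numeric(n - length(h)))
  corr <- Re(stats::fft(stats::fft(x) * Conj(stats::fft(hp)), inverse = TRUE)) / n
  corr[seq(1, n, by = 2)]
}

# Transpose of the analysis step: upsample by 2 and periodically convolve.
.wp_synthesis_step <- function(a, h, n_out) {
  u <- numeric(n_out)
  u[seq(1, n_out, by = 2)] <- a
  hp <- c(h, numeric(n_out - length(h)))
  Re(stats::fft(stats::fft(u) * stats::fft(hp), inverse = TRUE)) / n_out
}

# Full wavelet-packet tree to `level`; returns list of 2^level coefficient
# vectors in natural (filter-path) order, paths as 0/1 matrices.
wp_decompose <- function(x, level) {
  if (length(x) %% 2^level != 0 || length(x) < 2^level) {
    stop("signal length must be a positive multiple of 2^level")
  }
  nodes <- list(x)
  for (l in seq_len(level)) {
    nxt <- vector("list", 2 * length(nodes))
    for (i in seq_along(nodes)) {
      nxt[[2 * i - 1]] <- .wp_analysis_step(nodes[[i]], DB4_DEC_LO)
      nxt[[2 * i]] <- .wp_analysis_step(nodes[[i]], DB4_DEC_HI)
    }
    nodes <- nxt
  }
  nodes
}

# Reconstruct a single terminal node (natural index, 1-based) to full length.
wp_reconstruct_node <- function(coeffs, natural_index, level, n) {
  bits <- as.integer(intToBits(natural_index - 1))[level:1]  # b1..bL, b1 = top
  y <- coeffs
  for (l in level:1) {
    h <- if (bits[l] == 0) DB4_DEC_LO else DB4_DEC_HI
    y <- .wp_synthesis_step(y, h, length(y) * 2)
  }
  stopifnot(length(y) == n)
  y
}

# Sequency (frequency) index of a terminal node, 0-based: accounts for the
# spectral inversion of each downsampled high-pass branch (Gray-code order).
wp_frequency_index <- function(natural_index, level) {
  bits <- as.integer(intToBits(natural_index - 1))[level:1]
  f <- 0
  for (b in bits) f <- if (f %% 2 == 0) 2 * f + b else 2 * f + (1 - b)
  f
}

# Indices (natural order) of terminal nodes covering [lo, hi) Hz.
wp_band_nodes <- function(level, fs, lo, hi) {
  bw <- (fs / 2) / 2^level
  nat <- seq_len(2^level)
  f <- vapply(nat, wp_frequency_index, numeric(1), level = level)
  nat[f * bw >= lo & f * bw < hi]
}

#' Alpha-band signal by wavelet-packet reconstruction
#'
#' Resamples the channel to 128 Hz, performs a five-level db4
#' wavelet-packet decomposition (2 Hz terminal bands) and reconstructs the
#' sum of the nodes spanning 8-14 Hz.
#'
#' @param x numeric EEG channel (microvolts).
#' @param fs sampling rate in Hz; must be 128 or an integer multiple of it.
#' @return numeric vector: the alpha-band component at 128 Hz (length
#'   truncated to a multiple of 32).
#' @export
alpha_band_signal <- function(x, fs) {
  if (fs != 128) {
    if (fs %% 128 != 0) stop("fs must be an integer multiple of 128 Hz")
    x <- decimate_by(x, fs / 128)
  }
  level <- 5
  n <- length(x) - length(x) %% 2^level
  if (n < 2^level) stop("signal too short for level-5 decomposition")
  x <- x[seq_len(n)]
  coeffs <- wp_decompose(x, level)
  out <- numeric(n)
  for (idx in wp_band_nodes(level, 128, 8, 14)) {
    out <- out + wp_reconstruct_node(coeffs[[idx]], idx, level, n)
  }
  out
}

#' Alpha-band power of an EEG channel
#'
#' Mean squared amplitude of the wavelet-packet alpha-band reconstruction
#' (see [alpha_band_signal()]).
#'
#' @inheritParams alpha_band_signal
#' @return alpha power in microvolts squared.
#' @export
alpha_power_wpd <- function(x, fs) {
  mean(alpha_band_signal(x, fs)^2)
}
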