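# Internal frequency-domain signal primitives used by both detectors.
#
# All filtering is done in the frequency domain with real, symmetric transfer
# functions, so every stage is exactly zero-phase. Band edges use a
# square-root raised-cosine amplitude taper centred on the nominal edge, which
# puts the half-power (-3 dB) point exactly at the configured cutoff.

#' Zero-phase band-pass filter with half-power edges
#'
#' Filters a real signal by multiplying its spectrum with a real transfer
#' function that is 1 inside the pass band, 0 outside, and rolls off through a
#' square-root raised-cosine taper of width `transition_hz` centred on each
#' band edge, so the amplitude gain at the nominal edge frequency is exactly
#' 1/sqrt(2) (half power).
#'
#' @param x numeric vector, the signal.
#' @param fs_hz sampling rate in Hz.
#' @param low_hz,high_hz nominal band edges in Hz (half-power points).
#' @param transition_hz total taper width in Hz around each edge.
#' @return filtered numeric vector, same length as `x`.
#' @keywords internal
fft_bandpass <- function(x, fs_hz, low_hz, high_hz, transition_hz = 20) {
  stopifnot(is.numeric(x), fs_hz > 0, low_hz < high_hz)
  if (high_hz >= fs_hz / 2) {
    stop("band upper edge ", high_hz, " Hz is not below Nyquist (fs = ",
         fs_hz, " Hz)")
  }
  n <- length(x)
  if (n < 2L) return(x)
  f <- fft_freqs(n, fs_hz)
  h2 <- edge_taper(abs(f), low_hz, transition_hz, rising = TRUE) *
    edge_taper(abs(f), high_hz, transition_hz, rising = FALSE)
  Re(stats::fft(stats::fft(x) * sqrt(h2), inverse = TRUE)) / n
}

# Power-gain taper: raised cosine from 0 to 1 (rising) or 1 to 0 (falling)
# across [edge - w/2, edge + w/2]; value exactly 0.5 at the edge.
edge_taper <- function(f, edge_hz, transition_hz, rising = TRUE) {
  w <- transition_hz / 2
  g <- 0.5 * (1 + cos(pi * (f - (edge_hz + w)) / (2 * w)))
  g[f <= edge_hz - w] <- 0
  g[f >= edge_hz + w] <- 1
  if (rising) g else 1 - g
}

# Frequencies of the DFT bins in Hz, signed (negative for the upper half).
fft_freqs <- function(n, fs_hz) {
  k <- as.numeric(0:(n - 1))
  k[k > n / 2] <- k[k > n / 2] - n
  k * as.numeric(fs_hz) / n
}

#' Analytic signal and amplitude envelope
#'
#' FFT implementation of the analytic signal (Hilbert transform): negative
#' frequencies are zeroed, positive frequencies doubled.
#'
#' @param x real numeric vector.
#' @return complex vector, the analytic signal; `Mod()` gives the envelope.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) return(as.complex(x))
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Anti-aliased resampling by Fourier truncation
#'
#' Resamples a real signal to a new rate by truncating (or zero-padding) its
#' spectrum, i.e. ideal low-pass anti-aliasing at the output Nyquist followed
#' by band-limited interpolation.
#'
#' @param x numeric vector.
#' @param fs_in,fs_out input and output sampling rates in Hz.
#' @return numeric vector of length `round(length(x) * fs_out / fs_in)`.
#' @keywords internal
fft_resample <- function(x, fs_in, fs_out) {
  stopifnot(fs_in > 0, fs_out > 0)
  n <- length(x)
  m <- as.integer(round(n * fs_out / fs_in))
  if (m == n) return(x)
  X <- stats::fft(x)
  Y <- complex(m)
  keep <- min(n, m)
  hi <- floor((keep - 1) / 2)        # positive-frequency bins kept (excl. DC)
  lo <- floor(keep / 2)              # negative-frequency bins kept
  Y[1] <- X[1]
  if (hi > 0) Y[2:(hi + 1)] <- X[2:(hi + 1)]
  if (lo > 0) Y[(m - lo + 1):m] <- X[(n - lo + 1):n]
  # A shared Nyquist bin (even keep) must stay real: split handled above by
  # keeping floor counts asymmetric; enforce conjugate symmetry numerically.
  Re(stats::fft(Y, inverse = TRUE)) * (m / n) / m
}

#' Gaussian smoothing with reflected edges
#'
#' @param x numeric vector.
#' @param fs_hz sampling rate in Hz.
#' @param sigma_s Gaussian kernel SD in seconds.
#' @return smoothed vector, same length.
#' @keywords internal
gauss_smooth <- function(x, fs_hz, sigma_s) {
  sigma_n <- sigma_s * fs_hz
  if (sigma_n <= 0) return(x)
  half <- max(1L, ceiling(4 * sigma_n))
  k <- stats::dnorm(seq(-half, half), sd = sigma_n)
  k <- k / sum(k)
  n <- length(x)
  pad <- pmin(half, n - 1L)
  xp <- c(rev(x[seq_len(pad) + 1L]), x, rev(x[(n - pad):(n - 1L)]))
  out <- conv_same(xp, k)
  out[(pad + 1L):(pad + n)]
}

# Linear convolution via FFT, returning the "same"-length central part
# (kernel assumed odd-length, centred).
conv_same <- function(x, k) {
  n <- length(x); m <- length(k)
  nf <- stats::nextn(n + m - 1L, 2)
  y <- Re(stats::fft(stats::fft(c(x, numeric(nf - n))) *
                       stats::fft(c(k, numeric(nf - m))), inverse = TRUE)) / nf
  half <- (m - 1L) %/% 2L
  y[(half + 1L):(half + n)]
}

#' Morlet wavelet time-frequency power map
#'
#' Continuous wavelet transform with complex Morlet atoms of a fixed number of
#' cycles; each wavelet is L2-normalized so that background power is
#' comparable across frequencies.
#'
#' @param x numeric vector.
#' @param fs_hz sampling rate in Hz.
#' @param freqs_hz numeric vector of analysis frequencies.
#' @param n_cycles wavelet width in cycles (default 7).
#' @return matrix `length(freqs_hz)` x `length(x)` of power values.
#' @keywords internal
morlet_power <- function(x, fs_hz, freqs_hz, n_cycles = 7) {
  n <- length(x)
  out <- matrix(0, nrow = length(freqs_hz), ncol = n)
  for (i in seq_along(freqs_hz)) {
    f <- freqs_hz[i]
    sigma_t <- n_cycles / (2 * pi * f)
    half <- max(3L, ceiling(3.5 * sigma_t * fs_hz))
    t <- seq(-half, half) / fs_hz
    w <- exp(-t^2 / (2 * sigma_t^2)) * exp(2i * pi * f * t)
    w <- w / sqrt(sum(Mod(w)^2))
    cr <- conv_same(x, Re(w))
    ci <- conv_same(x, Im(w))
    out[i, ] <- cr^2 + ci^2
  }
  out
}

# Log-spaced frequency grid for the time-frequency stages.
tf_freq_grid <- function(low_hz, high_hz, n = 40) {
  exp(seq(log(low_hz), log(high_hz), length.out = n))
}
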