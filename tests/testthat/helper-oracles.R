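# Independent oracles used across the suite.  These deliberately avoid the
# package's own DSP code paths: plain fft/acf arithmetic only.

# Short-time FFT peak tracking: frequency of the largest-magnitude bin of a
# Hann-windowed frame centered at time t (seconds).
stft_peak <- function(wave, t, nfft = 1024) {
  fs <- wave$fs
  c0 <- round(t * fs) - nfft %/% 2
  seg <- wave$samples[(c0 + 1):(c0 + nfft)]
  win <- 0.5 * (1 - cos(2 * pi * seq(0, nfft - 1) / (nfft - 1)))
  mag <- Mod(stats::fft(seg * win))[1:(nfft %/% 2)]
  (which.max(mag) - 1) * fs / nfft
}

# Mean power spectral density (periodogram average) of x in [f_lo, f_hi] Hz.
band_power <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  keep <- f >= f_lo & f <= f_hi & f < fs / 2
  mean(p[keep])
}

# Hilbert envelope via the analytic signal (frequency-domain construction).
hilbert_env <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

expect_waveform <- function(w, fs = NULL) {
  expect_s3_class(w, "Waveform")
  expect_true(all(is.finite(w$samples)))
  if (!is.null(fs)) expect_equal(w$fs, fs)
  expect_lt(max(abs(w$samples)), 1)
}

ref_chirp <- function(fs = 44100) make_chirp(20, 12000, 1, 0.1, 0.02, fs)
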