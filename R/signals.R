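#' Log-frequency chirp
#'
#' Generates a chirp whose instantaneous frequency sweeps at a constant rate
#' in log-Hz from `f0` to `f1`, with raised-cosine onset/offset ramps.  The
#' canonical demo stimulus is a 1-s sweep from 20 Hz to 12 kHz with peak
#' amplitude 0.1 and 20-ms ramps at 44.1 kHz.
#'
#' The instantaneous frequency is f(t) = f0 * (f1/f0)^(t/T); its phase is the
#' closed-form integral 2*pi*f0*T/log(f1/f0) * ((f1/f0)^(t/T) - 1).
#'
#' @param f0,f1 Start and end frequency in Hz; `0 < f0 <= f1 < fs/2`.
#' @param duration Duration in s.
#' @param peak Peak amplitude before ramping, in (0, 1).
#' @param ramp Raised-cosine ramp length in s (each end); `2*ramp <= duration`.
#' @param fs Sampling rate in Hz.
#' @return A [waveform()].
#' @examples
#' ch <- make_chirp(20, 12000, 1, peak = 0.1, ramp = 0.02, fs = 44100)
#' max(abs(ch$samples))
#' @export
make_chirp <- function(f0, f1, duration, peak = 0.1, ramp = 0.02, fs = 44100) {
  if (f0 <= 0 || f1 < f0) stop("need 0 < f0 <= f1")
  if (f1 >= fs / 2) stop("f1 must be below the Nyquist frequency fs/2")
  if (peak <= 0 || peak >= 1) stop("peak must lie in (0, 1)")
  if (2 * ramp > duration) stop("2*ramp must not exceed duration")
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  if (f1 > f0) {
    k <- log(f1 / f0)
    phase <- 2 * pi * f0 * duration / k * (exp(k * t / duration) - 1)
  } else {
    phase <- 2 * pi * f0 * t            # degenerate chirp: a pure tone
  }
  x <- peak * sin(phase)
  waveform(apply_ramps(x, ramp, fs), fs)
}

#' Ramped pure tone
#'
#' A sinusoid with raised-cosine onset/offset ramps, scaled so that its rms
#' over the full duration equals `rms` (behavioral stimuli in this model are
#' 100-ms tones with 5-ms ramps).
#'
#' @param freq Tone frequency in Hz (below fs/2).
#' @param duration Duration in s.
#' @param ramp Ramp length in s (each end).
#' @param fs Sampling rate in Hz.
#' @param rms Target rms amplitude.
#' @return A [waveform()].
#' @export
make_tone <- function(freq, duration = 0.1, ramp = 0.005, fs = 22050,
                      rms = 0.05) {
  if (freq >= fs / 2) stop("freq must be below the Nyquist frequency fs/2")
  if (2 * ramp > duration) stop("2*ramp must not exceed duration")
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  x <- apply_ramps(sin(2 * pi * freq * t), ramp, fs)
  cur <- sqrt(mean(x^2))
  x <- x * (rms / cur)
  if (max(abs(x)) >= 1)
    stop("requested rms drives samples to |x| >= 1; lower it")
  waveform(x, fs)
}

#' Gaussian noise with a specified spectral shape
#'
#' White (flat spectrum), pink (power density proportional to 1/f, i.e.
#' -3 dB/octave) or speech-shaped noise (an LTASS-like tilt: flat below
#' 500 Hz, -9 dB/octave above).  Pink and speech-shaped noise are produced by
#' frequency-domain shaping of white Gaussian noise; the DC bin is zeroed.
#' Output is deterministic for a fixed seed.
#'
#' @param kind One of `"white"`, `"pink"`, `"speech_shaped"`.
#' @param duration Duration in s (> 0).
#' @param fs Sampling rate in Hz.
#' @param rms Target rms amplitude.
#' @param seed Integer seed.
#' @return A [waveform()].
#' @examples
#' nz <- make_noise("pink", 0.5, fs = 22050, rms = 0.05, seed = 1)
#' @export
make_noise <- function(kind = c("white", "pink", "speech_shaped"),
                       duration, fs = 22050, rms = 0.1, seed = 1) {
  kind <- match.arg(kind)
  if (duration <= 0) stop("duration must be positive")
  n <- round(duration * fs)
  x <- with_seed(seed, stats::rnorm(n))
  if (kind != "white") {
    X <- stats::fft(x)
    f <- (seq_len(n) - 1) * fs / n
    # fold to two-sided physical frequency, keep conjugate symmetry
    f2 <- pmin(f, fs - f)
    g <- rep(0, n)
    pos <- f2 > 0
    if (kind == "pink") {
      g[pos] <- 1 / sqrt(f2[pos])
    } else {
      # flat to 500 Hz, then -9 dB/oct in power: |H| = (f/500)^(-9/(20 log10 2))
      g[pos] <- pmin(1, (f2[pos] / 500)^(-9 / (20 * log10(2))))
    }
    x <- Re(stats::fft(X * g, inverse = TRUE)) / n
  }
  x <- x * (rms / sqrt(mean(x^2)))
  waveform(x, fs)
}

#' Word-like harmonic token
#'
#' A deterministic stand-in for a short spoken word: a harmonic complex at
#' fundamental `f0` shaped by three formant-like resonances (500, 1500,
#' 2500 Hz), amplitude-modulated at a syllable-like 4 Hz with a raised-cosine
#' envelope, with per-seed random harmonic phases.  Energy spans several
#' vocoder bands, which is what the correlation-map analyses require.
#'
#' @param duration Duration in s.
#' @param fs Sampling rate in Hz.
#' @param f0 Fundamental frequency in Hz.
#' @param seed Integer seed (randomizes harmonic phases only).
#' @param rms Target rms amplitude.
#' @return A [waveform()].
#' @export
make_word_like <- function(duration = 0.5, fs = 22050, f0 = 120, seed = 1,
                           rms = 0.05) {
  if (duration <= 0) stop("duration must be positive")
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  harmonics <- seq(f0, min(8000, fs / 2 * 0.9), by = f0)
  phases <- with_seed(seed, stats::runif(length(harmonics), 0, 2 * pi))
  formants <- c(500, 1500, 2500)
  bw <- c(80, 120, 160)
  x <- numeric(n)
  for (k in seq_along(harmonics)) {
    fk <- harmonics[k]
    amp <- sum(bw^2 / ((fk - formants)^2 + bw^2))   # resonance-like envelope
    x <- x + amp * sin(2 * pi * fk * t + phases[k])
  }
  am <- 0.5 * (1 - cos(2 * pi * 4 * t))             # 4-Hz raised-cosine AM
  x <- x * am
  x <- apply_ramps(x, 0.01, fs)
  x <- x * (rms / sqrt(mean(x^2)))
  if (max(abs(x)) >= 1) stop("requested rms drives samples to |x| >= 1")
  waveform(x, fs)
}

#' Mix a signal with noise at a prescribed SNR
#'
#' Scales the noise so that `20*log10(rms(signal)/rms(noise)) == snr_db` and
#' adds it to the signal; the signal samples are never altered (unless the
#' whole mixture is rescaled, see below).  `snr_db = Inf` returns the signal
#' unchanged ("quiet").  Noise longer than the signal is center-trimmed.
#'
#' If the mixture peaks at or above digital full scale the function errors,
#' unless `rescale = TRUE`, in which case the whole mixture (signal and noise
#' components alike, so the SNR is preserved) is scaled to peak 0.99 and the
#' scale factor is recorded in the `"scale"` attribute.
#'
#' @param signal,noise `Waveform`s at the same sampling rate; `noise` at least
#'   as long as `signal`.
#' @param snr_db Signal-to-noise ratio in dB (may be `Inf`).
#' @param rescale If `TRUE`, rescale an over-full-scale mixture instead of
#'   erroring.
#' @return A [waveform()]; attributes `"signal"` and `"noise"` hold the scaled
#'   components actually summed, and `"scale"` the global rescale factor
#'   (1 when no rescaling occurred).
#' @export
mix_at_snr <- function(signal, noise, snr_db, rescale = FALSE) {
  stopifnot(inherits(signal, "Waveform"))
  if (is.infinite(snr_db) && snr_db > 0) {
    out <- signal
    attr(out, "signal") <- signal$samples
    attr(out, "noise") <- numeric(length(signal$samples))
    attr(out, "scale") <- 1
    return(out)
  }
  stopifnot(inherits(noise, "Waveform"))
  if (signal$fs != noise$fs) stop("signal and noise sampling rates differ")
  ns <- length(signal$samples); nn <- length(noise$samples)
  if (nn < ns) stop("noise must be at least as long as the signal")
  off <- (nn - ns) %/% 2
  nse <- noise$samples[(off + 1):(off + ns)]
  g <- rms(signal$samples) / rms(nse) * 10^(-snr_db / 20)
  nse <- nse * g
  mixed <- signal$samples + nse
  sc <- 1
  if (max(abs(mixed)) >= 1) {
    if (!rescale)
      stop("mixture peaks at |x| >= 1; pass rescale = TRUE to scale to 0.99")
    sc <- 0.99 / max(abs(mixed))
    mixed <- mixed * sc
    nse <- nse * sc
  }
  out <- waveform(mixed, signal$fs)
  attr(out, "signal") <- signal$samples * sc
  attr(out, "noise") <- nse
  attr(out, "scale") <- sc
  out
}

#' Scale a waveform to a target rms
#'
#' Vocoded stimuli are equated for rms energy across conditions so that level
#' (audibility) differences do not confound waveform-degradation effects.
#'
#' @param wave A `Waveform`, not identically zero.
#' @param target_rms Target rms amplitude.
#' @return A scaled [waveform()] with `rms(out) == target_rms` (to within
#'   floating point).
#' @export
rms_equalize <- function(wave, target_rms) {
  stopifnot(inherits(wave, "Waveform"))
  cur <- rms(wave)
  if (cur == 0)
    stop("no energy to equalize: input waveform is identically zero")
  waveform(wave$samples * (target_rms / cur), wave$fs)
}

# Raised-cosine onset/offset ramps applied in place.
apply_ramps <- function(x, ramp, fs) {
  nr <- round(ramp * fs)
  if (nr > 0) {
    env <- 0.5 * (1 - cos(pi * (seq_len(nr) - 0.5) / nr))
    x[seq_len(nr)] <- x[seq_len(nr)] * env
    n <- length(x)
    x[(n - nr + 1):n] <- x[(n - nr + 1):n] * rev(env)
  }
  x
}
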