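#' Vocoder configuration
#'
#' Collects the free parameters of the stochastic-undersampling vocoder.
#' `N` is the number of independent stochastic samplers ("afferent fibres")
#' per frequency band; the total sampler budget is `N_TOTAL = n_bands * N`.
#'
#' @param n_bands Number of filterbank bands (default 10).
#' @param N Samplers per band, integer >= 0.  `N = 0` models a "dead" cochlea
#'   with no functional afferents: the vocoder output is exactly zero.
#' @param f_min,f_max Filterbank frequency range in Hz.
#' @param order Butterworth prototype order per band.
#' @param seed Master seed; it fully determines the vocoder output for a
#'   given input (one independent stream per band, or per band-and-sampler
#'   pair on the literal path).
#' @param equalize_rms If `TRUE`, scale the output to the input's rms.
#' @param control If `TRUE`, bypass the stochastic stage (every spike
#'   present): the output is the plain filterbank analysis-synthesis of the
#'   input and serves as the reference for all comparisons.
#' @param literal If `TRUE`, materialize all `N` Bernoulli trains per band and
#'   OR them; if `FALSE` (default), draw the aggregated train directly from
#'   its exact distribution, `P(spike) = 1 - (1 - |x|)^N`, one Uniform per
#'   sample.  The two paths are distributionally identical.
#' @return A `VocoderConfig` list.
#' @export
vocoder_config <- function(n_bands = 10, N = 300, f_min = 100, f_max = 10000,
                           order = 4, seed = 1, equalize_rms = FALSE,
                           control = FALSE, literal = FALSE) {
  stopifnot(n_bands >= 1, N >= 0, N == round(N))
  structure(list(n_bands = as.integer(n_bands), N = as.integer(N),
                 f_min = f_min, f_max = f_max, order = as.integer(order),
                 seed = as.integer(seed), equalize_rms = isTRUE(equalize_rms),
                 control = isTRUE(control), literal = isTRUE(literal)),
            class = "VocoderConfig")
}

#' @export
print.VocoderConfig <- function(x, ...) {
  cat(sprintf(
    "<VocoderConfig> %d band(s) %g-%g Hz, N = %d (N_TOTAL = %d), order %d, seed %d%s%s\n",
    x$n_bands, x$f_min, x$f_max, x$N, x$n_bands * x$N, x$order, x$seed,
    if (x$control) ", control" else "",
    if (x$equalize_rms) ", rms-equalized" else ""))
  invisible(x)
}

#' Stochastic spike train from a band signal
#'
#' One "afferent fibre": at every sample, compare the full-wave rectified
#' amplitude with an independent Uniform(0,1) draw and emit a unity spike when
#' the amplitude exceeds it, so `P(spike at t) = |x[t]|` exactly.  Requires
#' every `|sample| < 1`; larger amplitudes would silently saturate the
#' probability and are rejected.
#'
#' @param band_signal A `Waveform` with all `|samples| < 1`.
#' @param seed Integer seed for this sampler's stream.
#' @return A `SpikeTrain`: list with binary vector `spikes` and `fs`.
#' @export
stochastic_spike_train <- function(band_signal, seed) {
  stopifnot(inherits(band_signal, "Waveform"))
  assert_unit_range(band_signal)
  a <- abs(band_signal$samples)
  sp <- with_seed(seed, as.numeric(stats::runif(length(a)) < a))
  structure(list(spikes = sp, fs = band_signal$fs), class = "SpikeTrain")
}

#' OR-aggregate spike trains
#'
#' Sample-wise logical OR across trains: the aggregate fires wherever any
#' sampler fired.  The OR (rather than the mean) makes the reconstruction
#' converge to the original signal as the number of trains grows.
#'
#' @param trains Non-empty list of equal-length `SpikeTrain`s.
#' @return A `SpikeTrain`.
#' @export
aggregate_or <- function(trains) {
  if (length(trains) == 0) stop("cannot aggregate an empty list of trains")
  lens <- vapply(trains, function(tr) length(tr$spikes), integer(1))
  if (length(unique(lens)) != 1) stop("spike trains differ in length")
  agg <- Reduce(`pmax`, lapply(trains, `[[`, "spikes"))
  structure(list(spikes = agg, fs = trains[[1]]$fs), class = "SpikeTrain")
}

#' Aggregated spike probability
#'
#' Probability that at least one of `N` independent samplers fires on a sample
#' of rectified amplitude `a`: `1 - (1 - a)^N`.  Monotone increasing in both
#' arguments; this single expression explains why large `N` recovers the
#' waveform (probability approaches 1 for any a > 0) and why low-amplitude
#' features need more samplers than high-amplitude ones.
#'
#' @param a Rectified amplitude(s) in `[0, 1)`.
#' @param N Number of samplers, integer >= 0.
#' @return Probability in `[0, 1]`, vectorized over `a`.
#' @examples
#' spike_probability(0.5, 2)    # 0.75
#' spike_probability(0.1, 300)  # ~ 1
#' @export
spike_probability <- function(a, N) {
  stopifnot(N >= 0, N == round(N))
  if (any(a < 0 | a >= 1)) stop("amplitude must lie in [0, 1)")
  1 - (1 - a)^N
}

#' Reconstruct a band signal from its aggregated spike train
#'
#' Sample-wise multiplication of the spike train with the band signal: where
#' a spike occurred, the original amplitude and sign are restored; elsewhere
#' the sample is zero.
#'
#' @param spikes A `SpikeTrain`.
#' @param band_signal A `Waveform` of the same length.
#' @return A [waveform()].
#' @export
reconstruct_band <- function(spikes, band_signal) {
  stopifnot(inherits(spikes, "SpikeTrain"), inherits(band_signal, "Waveform"))
  if (length(spikes$spikes) != length(band_signal$samples))
    stop("spike train and band signal lengths differ")
  waveform(spikes$spikes * band_signal$samples, band_signal$fs)
}

#' Run the stochastic-undersampling vocoder
#'
#' Per band: bandpass-filter the input, draw the aggregated spike train of
#' `N` independent per-sample Bernoulli samplers (probability = rectified
#' amplitude), multiply the train back onto the band signal, re-filter
#' through the same bandpass (removing the energy splatter the sampling
#' introduces), and finally sum the band outputs.  With `control = TRUE` the
#' spike train is forced to all-ones, so the output is the deterministic
#' analysis-synthesis reference.
#'
#' @param wave Input `Waveform`; every `|sample| < 1`.
#' @param config A [vocoder_config()].
#' @param filterbank Optional pre-designed [design_filterbank()] matching
#'   `config` (re-designing the bank is the dominant cost when vocoding many
#'   short signals).
#' @return A [waveform()] of the same length and rate.
#' @examples
#' w <- make_tone(1000, 0.1, fs = 22050, rms = 0.05)
#' v <- vocode(w, vocoder_config(N = 300, seed = 7))
#' @export
vocode <- function(wave, config, filterbank = NULL) {
  stopifnot(inherits(wave, "Waveform"), inherits(config, "VocoderConfig"))
  assert_unit_range(wave)
  fb <- filterbank
  if (is.null(fb)) {
    fb <- design_filterbank(config$n_bands, config$f_min, config$f_max,
                            config$order, wave$fs)
  } else {
    stopifnot(inherits(fb, "FilterBank"))
    if (fb$fs != wave$fs) stop("filterbank designed for a different fs")
    if (length(fb$bands) != config$n_bands)
      stop("filterbank band count does not match config")
  }
  n <- length(wave$samples)
  out <- numeric(n)
  for (b in seq_len(config$n_bands)) {
    band <- fb$bands[[b]]
    y <- sosfilt(band$sos, wave$samples)
    if (config$control) {
      recon <- y
    } else if (config$N == 0L) {
      recon <- numeric(n)
    } else {
      ay <- abs(y)
      if (max(ay) >= 1)
        stop("band signal reached |x| >= 1; probability semantics violated")
      if (config$literal) {
        agg <- numeric(n)
        for (s in seq_len(config$N)) {
          u <- with_seed(derive_seed(config$seed, b, s),
                         stats::runif(n))
          agg <- pmax(agg, as.numeric(u < ay))
        }
      } else {
        p <- 1 - (1 - ay)^config$N
        agg <- with_seed(derive_seed(config$seed, b, 0L),
                         as.numeric(stats::runif(n) < p))
      }
      recon <- agg * y
    }
    out <- out + sosfilt(band$sos, recon)
  }
  res <- waveform_allow_zero(out, wave$fs)
  if (config$equalize_rms) res <- rms_equalize(res, rms(wave))
  res
}

# vocode with N = 0 legitimately returns all zeros; waveform() itself accepts
# zeros, this wrapper just documents the intent.
waveform_allow_zero <- function(samples, fs) waveform(samples, fs)
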