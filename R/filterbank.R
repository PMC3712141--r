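#' Design a Butterworth bandpass filter as second-order sections
#'
#' Analog Butterworth lowpass prototype of the given order, lowpass-to-bandpass
#' transformed (doubling the pole count), then discretized with the bilinear
#' transform using prewarped edge frequencies.  Returned as a cascade of
#' biquads (second-order sections) for numerical stability — the package never
#' expands the transfer function to a single high-order polynomial.
#'
#' "Fourth-order Butterworth bandpass" is read as a 4th-order lowpass
#' prototype (8 poles after the bandpass transformation); pass `order = 2` for
#' the alternative order-4-total reading.
#'
#' @param f_lo,f_hi Band edges in Hz, `0 < f_lo < f_hi < fs/2`.  The magnitude
#'   response is -3 dB at both edges.
#' @param fs Sampling rate in Hz.
#' @param order Prototype (lowpass) order; default 4.
#' @return A matrix with one row per section and columns
#'   `b0, b1, b2, a1, a2` (each section's `a0` is normalized to 1).
#' @export
butter_bandpass <- function(f_lo, f_hi, fs, order = 4) {
  if (!(f_lo > 0 && f_lo < f_hi && f_hi < fs / 2))
    stop("need 0 < f_lo < f_hi < fs/2")
  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * f_lo / fs)            # prewarped analog edges
  w2 <- fs2 * tan(pi * f_hi / fs)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k - 1 + order) / (2 * order))  # LHP unit poles
  # lowpass -> bandpass: each prototype pole p yields the two roots of
  # s^2 - (p*bw) s + w0^2 = 0
  pa <- complex(0)
  for (p in proto) {
    half <- p * bw / 2
    d <- sqrt(half^2 - w0^2)
    pa <- c(pa, half + d, half - d)
  }
  za <- rep(0 + 0i, order)                    # order zeros at s = 0
  ka <- bw^order
  # bilinear transform
  pd <- (fs2 + pa) / (fs2 - pa)
  zd <- c((fs2 + za) / (fs2 - za), rep(-1 + 0i, order))  # s=Inf zeros -> z=-1
  kd <- ka * Re(prod(fs2 - za) / prod(fs2 - pa))
  zpk_to_sos(zd, pd, kd)
}

# Pair poles/zeros into biquads.  Structure is known here: `order` zeros at
# z=+1, `order` at z=-1, poles in conjugate pairs.  Each section gets one
# conjugate pole pair and the zero pair (+1, -1) => numerator z^2 - 1.
# Overall gain is spread evenly across sections.
zpk_to_sos <- function(z, p, k) {
  pos <- p[Im(p) > 0][order(-Mod(p[Im(p) > 0]))]
  if (2 * length(pos) != length(p))
    stop("expected poles in conjugate pairs")
  nsec <- length(pos)
  sos <- matrix(0, nsec, 5,
                dimnames = list(NULL, c("b0", "b1", "b2", "a1", "a2")))
  gsec <- rep(abs(k)^(1 / nsec), nsec)
  gsec[1] <- gsec[1] * sign(k)
  for (i in seq_len(nsec)) {
    pp <- pos[i]
    a1 <- -2 * Re(pp)
    a2 <- Mod(pp)^2
    sos[i, ] <- c(gsec[i], 0, -gsec[i], a1, a2)  # (z-1)(z+1) numerator
  }
  sos
}

# Causal forward filtering through an SOS cascade.  The FIR half of each
# biquad is a vectorized 3-tap convolution; the recursive half runs through
# stats::filter's C loop, so no compiled code is needed.
sosfilt <- function(sos, x) {
  y <- x
  n <- length(x)
  for (i in seq_len(nrow(sos))) {
    b0 <- sos[i, 1]; b1 <- sos[i, 2]; b2 <- sos[i, 3]
    a1 <- sos[i, 4]; a2 <- sos[i, 5]
    v <- b0 * y
    if (b1 != 0) v <- v + b1 * c(0, y[-n])
    if (b2 != 0) v <- v + b2 * c(0, 0, y[-c(n - 1, n)])
    y <- as.numeric(stats::filter(v, c(-a1, -a2), method = "recursive"))
  }
  y
}

# Complex frequency response of an SOS cascade at frequencies f (Hz).
sos_freq_response <- function(sos, f, fs) {
  sos <- unname(sos)
  z1 <- exp(-2i * pi * f / fs)
  h <- rep(1 + 0i, length(f))
  for (i in seq_len(nrow(sos))) {
    num <- sos[i, 1] + sos[i, 2] * z1 + sos[i, 3] * z1^2
    den <- 1 + sos[i, 4] * z1 + sos[i, 5] * z1^2
    h <- h * num / den
  }
  h
}

#' Logarithmically spaced bandpass filterbank
#'
#' `n_bands` adjacent Butterworth bandpass filters whose `n_bands + 1` edges
#' are logarithmically spaced between `f_min` and `f_max`; neighboring bands
#' share their cutoff frequency.  The default (10 bands, 100 Hz to 10 kHz,
#' 4th-order) mimics a coarse cochlear frequency decomposition.
#'
#' @param n_bands Number of bands (>= 1).
#' @param f_min,f_max Frequency range in Hz; `f_max < fs/2`.
#' @param order Butterworth prototype order per band.
#' @param fs Sampling rate in Hz.
#' @return A `FilterBank`: list with `edges` (length `n_bands + 1`), `bands`
#'   (list of `BandSpec`s: `f_lo`, `f_hi`, `order`, `sos`), and `fs`.
#' @examples
#' fb <- design_filterbank(10, 100, 10000, fs = 22050)
#' fb$edges
#' @export
design_filterbank <- function(n_bands = 10, f_min = 100, f_max = 10000,
                              order = 4, fs = 22050) {
  if (n_bands < 1) stop("n_bands must be >= 1")
  if (f_max >= fs / 2) stop("f_max must be below the Nyquist frequency fs/2")
  if (f_min <= 0 || f_min >= f_max) stop("need 0 < f_min < f_max")
  edges <- f_min * (f_max / f_min)^(seq(0, n_bands) / n_bands)
  bands <- lapply(seq_len(n_bands), function(k) {
    structure(list(f_lo = edges[k], f_hi = edges[k + 1], order = order,
                   sos = butter_bandpass(edges[k], edges[k + 1], fs, order)),
              class = "BandSpec")
  })
  structure(list(edges = edges, bands = bands, fs = fs), class = "FilterBank")
}

#' @export
print.FilterBank <- function(x, ...) {
  cat(sprintf("<FilterBank> %d band(s), %g-%g Hz @ %g Hz, order %d\n",
              length(x$bands), x$edges[1], x$edges[length(x$edges)], x$fs,
              x$bands[[1]]$order))
  invisible(x)
}

#' Filter a waveform through one band of a filterbank
#'
#' Causal forward filtering (not zero-phase): the vocoder presents its output
#' acoustically, so each band carries its natural group delay.
#'
#' @param wave A `Waveform`.
#' @param band A `BandSpec` (an element of `FilterBank$bands`).
#' @return A [waveform()] of the same length.
#' @export
band_filter <- function(wave, band) {
  stopifnot(inherits(wave, "Waveform"), inherits(band, "BandSpec"))
  waveform(sosfilt(band$sos, wave$samples), wave$fs)
}
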