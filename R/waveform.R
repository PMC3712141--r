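#' Waveform objects
#'
#' A `Waveform` is the universal signal carrier of the package: a finite
#' sequence of dimensionless amplitude samples (digital full scale, so any
#' signal destined for the vocoder must lie strictly inside (-1, +1)) together
#' with its sampling rate in Hz.
#'
#' @param samples Numeric vector of amplitudes.
#' @param fs Sampling rate in Hz (> 0).
#' @return An object of class `"Waveform"`: a list with elements `samples`
#'   and `fs`.
#' @examples
#' w <- waveform(sin(2 * pi * 440 * seq(0, 0.1, by = 1 / 8000)) * 0.5, 8000)
#' duration(w)
#' rms(w)
#' @export
waveform <- function(samples, fs) {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number")
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("a Waveform needs at least one sample")
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("samples must be finite")
  structure(list(samples = samples, fs = as.numeric(fs)), class = "Waveform")
}

#' @export
print.Waveform <- function(x, ...) {
  cat(sprintf("<Waveform> %d samples @ %g Hz (%.4g s), rms %.4g, peak %.4g\n",
              length(x$samples), x$fs, duration(x), rms(x),
              max(abs(x$samples))))
  invisible(x)
}

#' @export
length.Waveform <- function(x) length(x$samples)

#' Duration of a waveform in seconds
#' @param wave A `Waveform`.
#' @return Duration in seconds.
#' @export
duration <- function(wave) {
  stopifnot(inherits(wave, "Waveform"))
  length(wave$samples) / wave$fs
}

#' Root-mean-square amplitude
#'
#' All levels in this package are digital rms amplitudes (no SPL calibration).
#'
#' @param wave A `Waveform` or numeric vector.
#' @return The rms value.
#' @export
rms <- function(wave) {
  x <- if (inherits(wave, "Waveform")) wave$samples else as.numeric(wave)
  sqrt(mean(x^2))
}

#' Check the vocoder amplitude invariant
#'
#' The stochastic samplers compare rectified amplitudes against Uniform(0,1)
#' draws, so probability semantics require every |sample| < 1.
#'
#' @param wave A `Waveform`.
#' @return Invisibly `TRUE`; otherwise an error.
#' @export
assert_unit_range <- function(wave) {
  stopifnot(inherits(wave, "Waveform"))
  if (max(abs(wave$samples)) >= 1)
    stop("amplitude invariant violated: |sample| >= 1 ",
         "(peak = ", signif(max(abs(wave$samples)), 6), ")")
  invisible(TRUE)
}

# Run expr with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic 31-bit stream seed from a master seed and stream indices.
# Integer hashing done in doubles (exact below 2^53), so independent
# (band, sampler) streams never collide in practice and never overflow.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  h <- (as.numeric(seed) %% 2147483647) + 1
  for (k in seq_along(idx)) {
    h <- (h * 48271 + (as.numeric(idx[k]) + 1) * 2246822519) %% 2147483647
    h <- (h * 69621) %% 2147483647
  }
  as.integer(h %% 2147483647L) + 1L
}
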