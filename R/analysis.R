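#' Magnitude-squared coherence between two waveforms
#'
#' Welch-type estimate: both signals are split into Hann-windowed segments
#' with 50% overlap, and the averaged cross- and auto-spectra give
#' `Cxy(f) = |Pxy|^2 / (Pxx * Pyy)`, bounded in `[0, 1]`.  Coherence is a
#' frequency-resolved measure of the temporal correlation between two
#' signals across their spectral components; it is the statistic used to
#' compare vocoded stimuli with their control rendering.
#'
#' The 1024-sample default window gives ~43-Hz resolution at 44.1 kHz, enough
#' to resolve the 10-band structure while averaging over many segments.
#'
#' @param x,y `Waveform`s with equal sampling rate and length.
#' @param nfft Segment/window length in samples (Hann window).
#' @return A `CoherenceResult`: list with `freqs` (Hz, up to Nyquist) and
#'   `coherence` (same length, values in `[0, 1]`).
#' @examples
#' w <- make_noise("white", 1, fs = 8000, rms = 0.1, seed = 1)
#' co <- coherence(w, w)
#' range(co$coherence)   # exactly 1
#' @export
coherence <- function(x, y, nfft = 1024) {
  stopifnot(inherits(x, "Waveform"), inherits(y, "Waveform"))
  if (x$fs != y$fs) stop("sampling rates differ")
  if (length(x$samples) != length(y$samples)) stop("lengths differ")
  n <- length(x$samples)
  if (n < nfft) nfft <- 2^floor(log2(n))
  hop <- nfft %/% 2
  starts <- seq(1, n - nfft + 1, by = hop)
  win <- 0.5 * (1 - cos(2 * pi * seq(0, nfft - 1) / (nfft - 1)))
  segmat <- function(s) {
    m <- vapply(starts, function(i) s[i:(i + nfft - 1)] * win,
                numeric(nfft))
    stats::mvfft(m)
  }
  X <- segmat(x$samples)
  Y <- segmat(y$samples)
  pxx <- rowMeans(Mod(X)^2)
  pyy <- rowMeans(Mod(Y)^2)
  pxy <- rowMeans(X * Conj(Y))
  cxy <- Mod(pxy)^2 / (pxx * pyy)
  cxy[!is.finite(cxy)] <- 0
  keep <- seq_len(nfft %/% 2 + 1)
  structure(list(freqs = (keep - 1) * x$fs / nfft,
                 coherence = pmin(1, cxy[keep]),
                 nseg = length(starts)),
            class = "CoherenceResult")
}

#' @export
print.CoherenceResult <- function(x, ...) {
  cat(sprintf("<CoherenceResult> %d bins, %g-%g Hz, median %.4f (%d segments)\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              stats::median(x$coherence), x$nseg))
  invisible(x)
}

#' Lag-maximised temporal correlation R
#'
#' Maximum over lags `|tau| <= max_lag` of the normalized cross-correlation
#' between a control signal and a (possibly longer) vocoded signal, clamped
#' below at 0.  Both signals are mean-centered and the correlation is
#' normalized by the product of their overall energies, so `R` is invariant
#' to positive rescaling of either input and `R = 1` only for a time-shifted
#' copy.  The 10-ms default lag window absorbs causal filter group delay
#' without rewarding gross misalignment.
#'
#' @param control,vocoded `Waveform`s at the same rate; `vocoded` at least as
#'   long as `control` (shorter control is zero-padded).
#' @param max_lag Maximum |lag| examined, in seconds.
#' @return `R` in `[0, 1]`.
#' @export
temporal_correlation <- function(control, vocoded, max_lag = 0.01) {
  stopifnot(inherits(control, "Waveform"), inherits(vocoded, "Waveform"))
  if (control$fs != vocoded$fs) stop("sampling rates differ")
  if (length(vocoded$samples) < length(control$samples))
    stop("vocoded signal shorter than control")
  a <- control$samples - mean(control$samples)
  b <- vocoded$samples - mean(vocoded$samples)
  if (sum(a^2) == 0 || sum(b^2) == 0)
    stop("zero-energy input: correlation undefined")
  nb <- length(b)
  a <- c(a, numeric(nb - length(a)))
  L <- min(nb - 1, max(0, round(max_lag * control$fs)))
  # circular cross-correlation via FFT, then restrict to |lag| <= L
  nfft <- 2^ceiling(log2(2 * nb))
  cc <- Re(stats::fft(stats::fft(c(a, numeric(nfft - nb))) *
                      Conj(stats::fft(c(b, numeric(nfft - nb)))),
                      inverse = TRUE)) / nfft
  lags <- c(cc[1:(L + 1)], if (L > 0) cc[(nfft - L + 1):nfft])
  r <- max(lags) / sqrt(sum(a^2) * sum(b^2))
  min(1, max(0, r))
}

#' Temporal-correlation map over an SNR-by-N grid
#'
#' For each grid cell: scale the signal to `rms_level`, mix with a fresh
#' noise realization at the cell's SNR, vocode with the cell's `N` samplers
#' per band, and compute [temporal_correlation()] against the control-mode
#' rendering of the clean signal; average over `reps` repetitions (fresh
#' noise and vocoder streams each repetition, all derived from `seed`).
#'
#' Cells whose mixture would exceed digital full scale (high `rms_level`
#' combined with strongly negative SNR) are mixed with `rescale = TRUE`:
#' the whole mixture is scaled to peak 0.99, preserving the SNR.
#'
#' @param signal Clean `Waveform` (any level; it is rescaled to `rms_level`).
#' @param noise_kind Noise type passed to [make_noise()].
#' @param rms_level Signal rms before mixing.
#' @param snr_grid Numeric vector of SNRs in dB (may include `Inf` = quiet).
#' @param n_grid Integer vector of per-band sampler counts.
#' @param n_bands Filterbank size.
#' @param reps Repetitions averaged per cell.
#' @param seed Master seed.
#' @param f_min,f_max,order Filterbank parameters.
#' @return A `CorrelationMap`: list with `snr_grid`, `n_grid`, matrix `R`
#'   (rows = SNRs, columns = N values), `rms_level`, `n_bands`.
#' @export
correlation_map <- function(signal, noise_kind = "white", rms_level = 0.01,
                            snr_grid = seq(-20, 20, by = 5),
                            n_grid = c(1, 3, 10, 30, 100, 300, 1000),
                            n_bands = 10, reps = 10, seed = 1,
                            f_min = 100, f_max = 10000, order = 4) {
  stopifnot(inherits(signal, "Waveform"),
            length(snr_grid) >= 1, length(n_grid) >= 1, reps >= 1)
  sig <- rms_equalize(signal, rms_level)
  fb <- design_filterbank(n_bands, f_min, f_max, order, sig$fs)
  control <- vocode(sig, vocoder_config(n_bands = n_bands, N = 0,
                                        f_min = f_min, f_max = f_max,
                                        order = order, seed = seed,
                                        control = TRUE),
                    filterbank = fb)
  R <- matrix(NA_real_, length(snr_grid), length(n_grid),
              dimnames = list(paste0("snr_", snr_grid),
                              paste0("N_", n_grid)))
  for (i in seq_along(snr_grid)) {
    for (j in seq_along(n_grid)) {
      acc <- 0
      for (r in seq_len(reps)) {
        cell_seed <- derive_seed(seed, i, j, r)
        mixed <- if (is.infinite(snr_grid[i])) {
          sig
        } else {
          nz <- make_noise(noise_kind, duration(sig) * 1.5, sig$fs,
                           rms = 0.1, seed = derive_seed(cell_seed, 1L))
          mix_at_snr(sig, nz, snr_grid[i], rescale = TRUE)
        }
        voc <- vocode(mixed,
                      vocoder_config(n_bands = n_bands, N = n_grid[j],
                                     f_min = f_min, f_max = f_max,
                                     order = order,
                                     seed = derive_seed(cell_seed, 2L)),
                      filterbank = fb)
        acc <- acc + temporal_correlation(control, voc)
      }
      R[i, j] <- acc / reps
    }
  }
  structure(list(snr_grid = snr_grid, n_grid = n_grid, R = R,
                 rms_level = rms_level, n_bands = n_bands),
            class = "CorrelationMap")
}

#' @export
print.CorrelationMap <- function(x, ...) {
  cat(sprintf("<CorrelationMap> rms %g, %d band(s), %d SNR x %d N cells\n",
              x$rms_level, x$n_bands, length(x$snr_grid), length(x$n_grid)))
  print(round(x$R, 3))
  invisible(x)
}

#' Filter-count sweep at matched total sampler budget
#'
#' Repeats [correlation_map()] for several filterbank sizes while holding the
#' total number of samplers `N_TOTAL = n_bands * N` constant across maps, so
#' the maps are comparable cell-for-cell: each cell of each map uses
#' `N = N_TOTAL / n_bands` (rounded down with a warning when not divisible).
#'
#' @param signal Clean `Waveform`.
#' @param noise_kind Noise type for [make_noise()].
#' @param rms_level Signal rms before mixing.
#' @param snr_grid SNRs in dB.
#' @param n_total_grid Total sampler budgets (shared across maps).
#' @param band_counts Filterbank sizes to compare (e.g. `c(1, 5, 10, 20)`).
#' @param reps Repetitions per cell.
#' @param seed Master seed.
#' @return A list of `CorrelationMap`s, one per element of `band_counts`;
#'   each carries the `n_total_grid` as attribute `"n_total_grid"`.
#' @export
filter_count_sweep <- function(signal, noise_kind = "white",
                               rms_level = 0.001,
                               snr_grid = seq(-20, 20, by = 10),
                               n_total_grid = c(10, 100, 1000, 10000),
                               band_counts = c(1, 5, 10, 20),
                               reps = 10, seed = 1) {
  maps <- vector("list", length(band_counts))
  names(maps) <- paste0("bands_", band_counts)
  for (k in seq_along(band_counts)) {
    nb <- band_counts[k]
    n_per <- n_total_grid %/% nb
    if (any(n_total_grid %% nb != 0))
      warning("N_TOTAL not divisible by ", nb, " bands; rounding N down")
    if (any(n_per < 1))
      stop("N_TOTAL budget smaller than the number of bands")
    m <- correlation_map(signal, noise_kind, rms_level, snr_grid,
                         n_grid = n_per, n_bands = nb, reps = reps,
                         seed = derive_seed(seed, k))
    attr(m, "n_total_grid") <- n_total_grid
    maps[[k]] <- m
  }
  maps
}

#' Regenerate the computational content of the model's reference figures
#'
#' `"fig1"`/`"fig2"`: the 1-s log chirp (20 Hz-12 kHz, peak 0.1, 44.1 kHz)
#' vocoded with N = 10 / N = 300, in quiet and in 0 dB SNR pink noise, with
#' per-band traces and control-vs-vocoded coherence.  `"fig5"`: word-token
#' correlation maps at rms 0.1/0.01/0.001/0.0001.  `"fig6"`: filter-count
#' sweep (20/5/1 bands) at matched N_TOTAL.  Writes CSV tables and PNG plots
#' under `out_dir` and returns the computed objects invisibly.
#'
#' @param which One of `"fig1"`, `"fig2"`, `"fig5"`, `"fig6"`.
#' @param seed Master seed.
#' @param out_dir Output directory (created if missing).
#' @param reps,snr_grid,n_grid Optional overrides to shrink the fig5/fig6
#'   grids (the full grids take minutes).
#' @return Invisibly, a list of computed results.
#' @export
reproduce_figure <- function(which = c("fig1", "fig2", "fig5", "fig6"),
                             seed = 1, out_dir = "figures", reps = 3,
                             snr_grid = seq(-20, 20, by = 10),
                             n_grid = c(1, 10, 100, 1000)) {
  which <- match.arg(which)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (which %in% c("fig1", "fig2")) {
    N <- if (which == "fig1") 10L else 300L
    res <- chirp_demo(N, seed)
    utils::write.csv(data.frame(freq = res$quiet$coh$freqs,
                                coherence_quiet = res$quiet$coh$coherence,
                                coherence_noise = res$noise$coh$coherence),
                     file.path(out_dir, paste0(which, "_coherence.csv")),
                     row.names = FALSE)
    grDevices::png(file.path(out_dir, paste0(which, ".png")),
                   width = 900, height = 500)
    graphics::par(mfrow = c(1, 2))
    for (cond in c("quiet", "noise")) {
      co <- res[[cond]]$coh
      pos <- co$freqs > 0
      co <- list(freqs = co$freqs[pos], coherence = co$coherence[pos])
      graphics::plot(co$freqs, co$coherence, type = "l", log = "x",
                     xlim = c(50, 15000), ylim = c(0, 1),
                     xlab = "Frequency (Hz)", ylab = "Coherence",
                     main = sprintf("N = %d, %s", N, cond))
      graphics::abline(v = c(100, 10000), lty = 3)
    }
    grDevices::dev.off()
    return(invisible(res))
  }
  word <- make_word_like(0.5, fs = 22050, f0 = 120, seed = seed)
  if (which == "fig5") {
    levels <- c(0.1, 0.01, 0.001, 0.0001)
    maps <- lapply(seq_along(levels), function(i)
      correlation_map(word, "white", levels[i], snr_grid, n_grid,
                      n_bands = 10, reps = reps, seed = derive_seed(seed, i)))
    names(maps) <- paste0("rms_", levels)
    for (nm in names(maps))
      utils::write.csv(maps[[nm]]$R,
                       file.path(out_dir, paste0("fig5_", nm, ".csv")))
    plot_maps(maps, file.path(out_dir, "fig5.png"))
    return(invisible(maps))
  }
  # fig6: matched N_TOTAL across 20/5/1 bands (n_grid reused as N_TOTAL grid)
  maps <- filter_count_sweep(word, "white", 0.001, snr_grid,
                             n_total_grid = n_grid[n_grid >= 20],
                             band_counts = c(20, 5, 1), reps = reps,
                             seed = seed)
  for (nm in names(maps))
    utils::write.csv(maps[[nm]]$R,
                     file.path(out_dir, paste0("fig6_", nm, ".csv")))
  plot_maps(maps, file.path(out_dir, "fig6.png"))
  invisible(maps)
}

# Vocode the reference chirp in quiet and in 0 dB pink noise; return
# control/vocoded pairs and their coherences.
chirp_demo <- function(N, seed, fs = 44100) {
  ch <- make_chirp(20, 12000, 1, peak = 0.1, ramp = 0.02, fs = fs)
  fb <- design_filterbank(10, 100, 10000, 4, fs)
  ctrl_cfg <- vocoder_config(N = 0, seed = seed, control = TRUE)
  out <- list()
  for (cond in c("quiet", "noise")) {
    input <- if (cond == "quiet") {
      ch
    } else {
      mix_at_snr(ch, make_noise("pink", 1.5, fs, rms = 0.1,
                                seed = derive_seed(seed, 99L)), 0)
    }
    ctrl <- vocode(input, ctrl_cfg, filterbank = fb)
    voc <- vocode(input, vocoder_config(N = N, seed = derive_seed(seed, 7L)),
                  filterbank = fb)
    out[[cond]] <- list(input = input, control = ctrl, vocoded = voc,
                        coh = coherence(ctrl, voc))
  }
  out
}

plot_maps <- function(maps, path) {
  grDevices::png(path, width = 320 * length(maps), height = 320)
  graphics::par(mfrow = c(1, length(maps)))
  for (nm in names(maps)) {
    m <- maps[[nm]]
    graphics::image(seq_along(m$n_grid), seq_along(m$snr_grid),
                    t(m$R), zlim = c(0, 1),
                    col = grDevices::hcl.colors(64, "Blue-Red 3"),
                    xlab = "N index", ylab = "SNR index", main = nm)
  }
  grDevices::dev.off()
  invisible(path)
}
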