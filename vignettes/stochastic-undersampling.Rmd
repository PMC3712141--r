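---
title: "Stochastic undersampling of sound waveforms: model, assumptions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic undersampling of sound waveforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stochvoc)
```

## The model

Each afferent fibre of the auditory nerve can be viewed as emitting a
stochastically digitized copy of its driving waveform: at any instant the
probability of a spike grows with the instantaneous sound pressure.  A single
fibre therefore conveys a poor copy of low-amplitude or fast-varying features,
but a population of `N` fibres jointly recovers them (the volley principle).
Deafferentation — losing fibres — lowers `N` and should degrade exactly those
features, and more so in noise than in quiet.

`stochvoc` implements this idea as an analysis–synthesis vocoder:

1. **Analysis.** The input `x[t]` (digital amplitudes, `|x| < 1`) is filtered
   through `n_bands` adjacent Butterworth bandpass filters whose
   `n_bands + 1` cutoffs are logarithmically spaced between `f_min` and
   `f_max` (defaults: 10 bands, 100 Hz–10 kHz).  Neighbouring bands share
   their cutoff frequency.
2. **Stochastic sampling.** In each band, `N` independent samplers each emit a
   unity spike at sample `t` with probability `|y[t]|`, the full-wave
   rectified band amplitude, by comparison with an independent Uniform(0,1)
   draw.
3. **OR aggregation.** The `N` trains are combined sample-wise with a logical
   OR, so the aggregated spike probability is `1 - (1 - |y[t]|)^N`
   (`spike_probability()`).  The OR — rather than the mean — makes the
   reconstruction converge to the original band signal as `N` grows.
4. **Reconstruction.** The aggregated train is multiplied sample-wise with the
   band signal (restoring sign and amplitude where spikes occurred), the
   result is re-filtered through the *same* bandpass to remove the spectral
   splatter the sampling introduces, and the bands are summed.

`N = 0` models a dead cochlea (silence); the *control* condition runs the
identical pipeline with the spike train forced to all-ones, i.e. the plain
filterbank analysis–synthesis.  Implementing the control inside the pipeline
(rather than bypassing the filterbank) keeps the filterbank coloration
identical across conditions, so every comparison isolates the stochastic
stage.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `n_bands` | 10 | frequency channels; coarse cochlear decomposition |
| `N` | 300 | samplers ("fibres") per band; `N_TOTAL = n_bands * N` |
| `f_min`, `f_max` | 100, 10000 Hz | filterbank span; `f_max < fs/2` |
| `order` | 4 | Butterworth prototype order per band (see below) |
| `seed` | — | fully determines the output for a given input |
| `equalize_rms` | off | rescale output to the input rms, isolating waveform effects from audibility |

"Fourth-order Butterworth" is read as a 4th-order *lowpass prototype* (8 poles
after the bandpass transformation), the common reading of the phrase; passing
`order = 2` gives the alternative order-4-total reading.  Filtering is causal
and forward-only — the stimuli are meant to be playable, and zero-phase
filtering is not part of the method — so each band carries its natural group
delay; the analysis metrics tolerate that (below).

## Randomness and reproducibility

One master seed spawns an independent, reproducible stream per band (or per
band-and-sampler pair) through an integer-hash spawning scheme, so results do
not depend on evaluation order.  Two distributionally identical sampling
paths exist: the default draws the aggregated train directly with one
Uniform(0,1) per sample against `1 - (1 - |y|)^N`; `literal = TRUE`
materializes all `N` Bernoulli trains and ORs them.  The literal path costs
`N` times more random draws and exists so tests can confirm the equivalence.

Samples with `|x| >= 1` raise an error rather than clipping: the
comparison-with-Uniform(0,1) semantics silently saturates above 1, which
would hide level bugs.

## Analysis metrics

**Coherence.**  `coherence()` is a Welch magnitude-squared coherence: Hann
window of 1024 samples, 50% overlap, averaged periodograms.  The window
length is a stand-in choice — at 44.1 kHz it gives ~43 Hz resolution, fine
enough to resolve the 10-band structure while leaving many segments to
average.

**Temporal correlation `R`.**  `temporal_correlation()` is the maximum over
lags `|tau| <= 10` ms of the normalized cross-correlation between the control
rendering of the clean signal and a vocoded stimulus, clamped below at 0.
Whether the original statistic was computed at zero lag or maximised over
lags is not stated in its source; lag maximisation is the documented default
here because causal filter group delay shifts the vocoded output by a few
milliseconds, which should not read as degradation, while 10 ms is too short
to reward gross misalignment.  Negative maxima clamp to 0 to match the
`[0, 1]` scale of the correlation maps.  Note one consequence of lag
maximisation: a sign-inverted *periodic* signal re-aligns at a half-period
lag, so the clamp-to-zero behaviour is only observable at `max_lag = 0`.

**Correlation maps.**  `correlation_map()` scans SNR × N at a fixed signal
rms: each cell scales the clean signal, mixes it with a fresh noise
realization, vocodes, and correlates against the clean control; cells are
averaged over `reps = 10` repetitions (a map from a single realization is
noticeably grainy at small N).  Default grids — SNR from −20 to 20 dB in
5-dB steps, `N in {1, 3, 10, 30, 100, 300, 1000}` — span the printed ranges
of the reference analysis; the exact grid steps of the original maps are not
published, so these are stand-ins.  At high signal levels combined with very
negative SNRs the mixture would exceed digital full scale; those cells are
mixed with `rescale = TRUE` (whole mixture scaled to peak 0.99, SNR
preserved), the only interpretation under which the full published grid is
realizable inside the open-interval amplitude constraint.

**Filter-count sweeps.**  `filter_count_sweep()` repeats the map for several
filterbank sizes at a matched total budget `N_TOTAL = n_bands * N`, rounding
`N` down (with a warning) when the budget is not divisible.

## The synthetic stimuli

The generators emulate the stimuli of the reference experiments: a 1-s
log-frequency chirp (20 Hz–12 kHz, peak 0.1, 20-ms raised-cosine ramps,
44.1 kHz), 100-ms ramped tones, and seeded white / pink / speech-shaped
Gaussian noise.  Pink noise is made by frequency-domain shaping with
magnitude ∝ 1/√f (exact 3 dB/octave law, trivially testable); speech-shaped
noise approximates a long-term average speech spectrum as flat below 500 Hz
and −9 dB/octave above — the original speech-noise spectrum is unpublished,
and no human thresholds are reproduced here, so a documented simple shape
suffices.

The original word recording is not deposited, so
`make_word_like()` builds a labelled synthetic stand-in: a 0.5-s harmonic
complex at f0 = 120 Hz with three formant-like resonances (500/1500/2500 Hz,
bandwidths 80/120/160 Hz), 4-Hz raised-cosine amplitude modulation, and
per-seed random harmonic phases.  It shares with real speech the properties
the analysis needs — broadband energy across several vocoder bands, a
low-frequency-dominated spectrum, strong envelope modulation — and nothing
else: no formant transitions, no aperiodicity, no consonants.  A green
correlation-map test therefore establishes the qualitative SNR × N × level
structure of the model, not anything about intelligibility of real speech.

SNR is defined on rms over the full signal support (no voice-activity
detection is specified anywhere, and the token is modulated but never
silent).  Noise longer than the signal is center-trimmed before mixing.

## Numerical choices and degenerate inputs

* Filters are designed as cascaded second-order sections (bilinear transform
  of the analog bandpass); the transfer function is never expanded to a
  single high-order polynomial, which would be ill-conditioned for the
  narrow low-frequency bands.
* `mix_at_snr()` is exact: the realized SNR of the returned components
  matches the request to well under 1e-6 dB, and the signal samples are
  returned untouched (shy of a global rescale, which preserves SNR).
* All-zero waveforms: valid as vocoder input (N = 0 output is exactly zero),
  but `rms_equalize()` and `temporal_correlation()` reject them — there is
  no energy to scale or correlate.
* `spike_probability()` rejects amplitudes outside `[0, 1)` instead of
  clamping, mirroring the sampler's own error contract.

## Known limitations

The sampler is memoryless and level-linear: no refractoriness, adaptation,
saturation, phase-locking roll-off, or diversity of rate-level functions —
all explicitly outside the model, which isolates what stochasticity *per se*
does to waveform encoding.  Levels are digital rms only (no dB SPL mapping),
and behavioural quantities (detection thresholds, speech reception
thresholds) are out of scope: the package computes signal-level proxies
(coherence, R), not percent-correct.

## A worked example

```{r example, eval = FALSE}
ch <- make_chirp(20, 12000, 1, peak = 0.1, ramp = 0.02, fs = 44100)
ctrl <- vocode(ch, vocoder_config(N = 0, seed = 1, control = TRUE))
v300 <- vocode(ch, vocoder_config(N = 300, seed = 2))
co <- coherence(ctrl, v300)
median(co$coherence[co$freqs >= 100 & co$freqs <= 10000])
# ~ 0.9999: with 300 samplers per band the vocoded chirp is
# indistinguishable from the control, as the model predicts
```
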