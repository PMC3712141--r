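# stochvoc

A stochastic-undersampling ("deafferentation") vocoder and its analysis
toolkit, for computational auditory neuroscience and psychoacoustics.

## The problem

Each auditory-nerve fibre emits spikes stochastically, with an instantaneous
firing probability that grows with instantaneous sound pressure.  A single
fibre is therefore a poor copy of its driving waveform, but the aggregate of
`N` fibres innervating one cochlear region recovers it — the volley
principle.  Losing fibres (deafferentation, as in aging or after noise
exposure) lowers `N` without shifting audiometric thresholds, and should
selectively degrade low-amplitude and high-frequency waveform features, more
in noise than in quiet.

`stochvoc` turns that hypothesis into a signal-processing tool.  The input is
split by `n_bands` adjacent Butterworth bandpass filters with
logarithmically spaced shared cutoffs (default 10 bands, 100 Hz–10 kHz,
4th-order).  In each band, `N` independent samplers fire a unity spike at
sample `t` with probability `|y[t]|` (the rectified band amplitude compared
against Uniform(0,1) draws); the trains are OR-aggregated, so

    P(spike at t) = 1 − (1 − |y[t]|)^N,

multiplied back onto the band signal, re-filtered through the same bandpass,
and summed across bands.  As `N → ∞` the output converges to the control
(the same pipeline with all spikes present); small `N` turns weak and
fast-varying features into noise.  Fidelity is quantified by Welch
magnitude-squared coherence and by `R`, the lag-maximised normalized
cross-correlation (clamped to `[0, 1]`) between the vocoded stimulus and the
clean control.

## Worked example

```r
library(stochvoc)

ch   <- make_chirp(20, 12000, 1, peak = 0.1, ramp = 0.02, fs = 44100)
ctrl <- vocode(ch, vocoder_config(N = 0, seed = 1, control = TRUE))
v300 <- vocode(ch, vocoder_config(N = 300, seed = 2))
v10  <- vocode(ch, vocoder_config(N = 10,  seed = 3))

co300 <- coherence(ctrl, v300)
co10  <- coherence(ctrl, v10)
in_range <- function(co, lo, hi) co$freqs >= lo & co$freqs <= hi
median(co300$coherence[in_range(co300, 100, 10000)])  # 0.9999
median(co10$coherence [in_range(co10,  100, 10000)])  # 0.9441
mean(co10$coherence[in_range(co10,  100,   200)])     # 0.982
mean(co10$coherence[in_range(co10, 5000, 10000)])     # 0.896
```

With 300 samplers per band the vocoded chirp is essentially identical to the
control (median coherence 0.9999).  With 10 samplers the representation
degrades (0.944), and degrades more in the top octave (0.896) than in the
lowest (0.982): fast-varying features need more samplers.

```r
word <- make_word_like(0.5, 22050, f0 = 120, seed = 1)
m <- correlation_map(word, "white", rms_level = 0.01,
                     snr_grid = c(-10, 0, 10, 20),
                     n_grid = c(10, 100, 1000), reps = 5, seed = 1)
m$R
#>          N_10 N_100 N_1000
#> snr_-10 0.184 0.287  0.317
#> snr_0   0.523 0.732  0.739
#> snr_10  0.719 0.937  0.965
#> snr_20  0.735 0.952  0.996
```

`R` rises toward 1 with both SNR and `N` (0.996 in the optimal corner) and
collapses toward 0 as noise takes over — the waveform correlate of why
under-sampled ("deafferented") listeners struggle disproportionately in
noise.

## Command line

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "stochvoc.R", package = "stochvoc"))')" \
    gen --kind chirp --fs 44100 --dur 1 --peak 0.1 --out chirp.wav
# subcommands: gen | vocode | coherence | corrmap | sweep | figures
```

Every run with an explicit `--seed` is bit-reproducible and writes a JSON
manifest (parameters, seeds, output hashes) next to its outputs.

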