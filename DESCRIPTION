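Package: stochvoc
Title: Stochastic-Undersampling Vocoder for Modelling Auditory Deafferentation
Version: 0.1.0
Authors@R:
    person("Pablo", "Serrano", email = "pserrano@example.org", role = c("aut", "cre"))
Description: An analysis-synthesis vocoder in which each output of a
    logarithmically spaced Butterworth filterbank is sampled by N independent
    per-sample Bernoulli "spike" generators (firing probability equal to the
    rectified instantaneous amplitude), OR-aggregated, multiplied back onto the
    band signal, re-filtered and summed.  The construction emulates the loss of
    auditory-nerve afferent fibres (deafferentation): small N degrades
    low-amplitude and high-frequency waveform features, and does so more in
    noise than in quiet.  Includes generators for the synthetic stimuli used to
    probe the model (log-frequency chirps, ramped tones, white/pink/speech-shaped
    noise, a word-like harmonic token), SNR mixing and rms equalisation,
    magnitude-squared coherence and lag-maximised temporal-correlation metrics,
    SNR-by-N correlation maps at several signal levels, matched-budget
    filter-count sweeps, WAV input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
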