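Package: cisep
Title: Cochlear-Implant Sound Coding, Source Separation and Remixing Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating the ACE (advanced combination encoder) cochlear-implant
    sound-coding strategy and for studying source-separation based enhancement around it.
    Provides a deterministic ACE chain (adaptive gain control, FFT filterbank, band
    envelopes, loudness growth function, N-of-M channel selection, subject mapping to
    electrodograms), a decibel energy-ratio calculus for signal-to-interference and
    vocals-to-instruments enhancement in both the audio and the electrodogram domain
    (including the cross-domain equivalence table), objective metrics (per-channel linear
    correlation of electrodograms, scale-invariant SNR), Conv-TasNet-style separation
    networks trained with a built-in reverse-mode autodiff (time-domain and LGF-domain
    output variants), synthetic voice-like and instrument-like signal generators for
    controlled experiments, and front-end / end-to-end processing pipelines with a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
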