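# cisep: cochlear-implant sound coding, source separation and remixing

Cochlear implants (CIs) convey sound as patterns of electrical stimulation —
*electrodograms* — produced by a sound-coding strategy. For CI listeners,
concurrent talkers and background instruments are far more disruptive than for
normal-hearing listeners, so a long-standing idea is to separate the sources
and remix them at a more favourable ratio before (or inside) the coding
strategy. `cisep` is an R toolkit for studying exactly that, end to end:

* **ACE sound coding** — a deterministic simulation of the Advanced
  Combination Encoder chain: adaptive gain control, FFT filterbank (128-point,
  22 bands at 16 kHz by default), band envelope extraction, loudness growth
  function (LGF) compression, N-of-M maxima selection (8 of 22 by default),
  and subject mapping onto the electrical dynamic range `[THL, MCL]`.
  Every stage can be bypassed, which exposes a linear reference chain.
* **Enhancement calculus** — the decibel energy ratios used to quantify
  vocals-to-instruments (VIR) and signal-to-interference (SIR) enhancement,

  `VIR [dB] = 10 log10( Σ_n v[n]² / Σ_n i[n]² )`

  in the time domain, and

  `VIR_E [dB] = 10 log10( Σ_t Σ_m E_V(t,m)² / Σ_t Σ_m E_I(t,m)² )`

  in the electrodogram domain, together with split-gain remixing (a total of
  `g` dB applied as `+g/2` to the target and `−g/2` to the interferer) and the
  *equivalent enhancement* `VIR_eqi`: encode the separated tracks with the
  full ACE chain and measure their electrodogram-domain ratio. Because the
  LGF is compressive, equal front-end gain steps map to smaller
  electrodogram-domain steps; `build_equivalence_table()` tabulates the
  mapping.
* **Objective metrics** — per-channel Pearson correlation between
  electrodograms (LCC) with principled handling of never-stimulated channels,
  and scale-invariant SNR (SI-SNR) for waveforms.
* **Separation networks** — Conv-TasNet-style separators (encoder /
  dilated-TCN masker / decoder) in two variants: a *front-end* model emitting
  time-domain sources, and an *end-to-end* model whose decoder performs
  stepwise dimensionality reduction into per-source LGF frames. Models are
  built, trained (Adam; SI-SNR or MSE loss) and run with a small reverse-mode
  autodiff engine included in the package — no external deep-learning
  framework is required.
* **Synthetic material** — seed-deterministic voice-like surrogates
  (harmonic complexes with F0 drift, vibrato and syllabic modulation in
  canonical male/female ranges) and instrument-like beds (filtered noise,
  transient trains, sustained chords), mixed at prescribed SIR/VIR.
* **Pipelines + CLI** — `run_front_end_pipeline()` (separate → remix →
  encode) and `run_end_to_end_pipeline()` (separate to LGF frames → gain in
  the electrodogram domain → recombine → N-of-M), plus a `cisep` command-line
  tool (`encode`, `enhance`, `equivalence-table`, `evaluate`, `simulate`,
  `separate`, `run-front-end`, `run-end-to-end`, `train`).

## Worked example

```r
library(cisep)

# a synthetic vocals/instruments pair at 0 dB VIR
v <- gen_voice_like(voice_spec(duration = 1, seed = 11))
i <- gen_instrument_like(instrument_spec(duration = 1, seed = 12))

# encode the mixture with the default ACE strategy
mix <- mix_at_ratio(v, i, 0)
encode_ace(mix)
#> <electrodogram> 882 frames x 22 channels @ 888.9 frames/s [lgf], mean active/frame 3.74

# how much electrodogram-domain enhancement does a front-end gain produce?
build_equivalence_table(v, i, 0:8)
#> Front-end vs equivalent end-to-end enhancement (dB):
#>  front_end_db end_to_end_db
#>             0         2.806
#>             1         3.644
#>             2         4.491
#>             3         5.348
#>             4         6.212
#>             5         7.078
#>             6         7.943
#>             7         8.805
#>             8         9.665
```

The first column is the gain applied to the separated pair in the time domain
(split ±g/2); the second is the equivalent enhancement measured between the
two ACE-encoded electrodograms. The end-to-end column rises strictly but by
less than 1 dB per 1 dB front-end step: the loudness growth function
compresses level differences, which is why a nominally identical enhancement
must be *calibrated* rather than copied across the two pipeline domains.
(The 2.8 dB offset at 0 dB front-end gain says the coding strategy itself
already emphasizes this voice over this instrument bed.)

```r
# oracle-separation consistency: remixing at 0 dB reproduces plain ACE
it <- make_mixture_dataset(1, "music", 0, seed = 21, duration = 0.5)[[1]]
res <- run_front_end_pipeline(it$mixture, pipeline_config(
  ace_config(), list(type = "oracle", sources = it$sources),
  list(tag = "VIR", gain_db = 0, domain = "time")))
lcc_per_channel(res$electrodogram, encode_ace(it$mixture))
#> <lcc_result> mean r = 1.00000 over 22 defined channel(s) of 22
```

## Command-line interface

```sh
cisep encode mix.wav --config strategy.yaml --out mix.elec
cisep equivalence-table --target v.wav --interferer i.wav --steps 0:8:1 --out table.csv
cisep evaluate --ref ref.elec --est est.elec --out lcc.json
cisep simulate --task music --n 50 --ratio-db 5 --seed 7 --out-dir data/
```

The script is installed under `inst/exec/cisep`; it is a thin wrapper around
the exported `cisep_main()`.
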