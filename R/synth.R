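#' Voice-like source specification
#'
#' Parameters of the harmonic voice surrogate used in controlled
#' experiments: a harmonic complex whose fundamental wanders slowly inside
#' `f0_range`, with sinusoidal vibrato, spectral rolloff per octave, and
#' syllabic (raised-cosine) amplitude modulation. Canonical speech ranges:
#' male `[85, 155]` Hz, female `[165, 255]` Hz, giving the disjoint
#' fundamental-frequency structure that two-talker experiments rely on.
#'
#' @param f0_range fundamental-frequency interval in Hz, within (60, 500).
#' @param vibrato_rate vibrato rate (Hz). @param vibrato_depth depth in cents.
#' @param harmonic_rolloff spectral envelope decay in dB/octave.
#' @param syllable_rate amplitude-modulation rate (Hz).
#' @param duration seconds. @param seed integer seed.
#' @return an object of class `voice_spec`.
#' @export
voice_spec <- function(f0_range = c(165, 255), vibrato_rate = 5.5,
                       vibrato_depth = 25, harmonic_rolloff = 6,
                       syllable_rate = 4, duration = 1, seed = 1) {
  if (length(f0_range) != 2L || f0_range[1L] >= f0_range[2L] ||
      f0_range[1L] <= 60 || f0_range[2L] >= 500)
    stop("voice_spec: f0_range must be an increasing interval within (60, 500) Hz")
  if (duration <= 0) stop("voice_spec: duration must be > 0")
  structure(list(f0_range = f0_range, vibrato_rate = vibrato_rate,
                 vibrato_depth = vibrato_depth, harmonic_rolloff = harmonic_rolloff,
                 syllable_rate = syllable_rate, duration = duration,
                 seed = as.integer(seed)),
            class = "voice_spec")
}

#' Instrument-like source specification
#'
#' A background "bed" assembled from components: band-limited noise
#' (`list(type = "noise_band", band = c(lo, hi))`), a decaying transient
#' train (`list(type = "transient_train", rate = r)`), and/or a sustained
#' chord (`list(type = "chord", fundamentals = c(...))`). Stands in for
#' bass/drums/other accompaniment stems.
#'
#' @param components non-empty list of component descriptors (above).
#' @param duration seconds. @param seed integer seed.
#' @return an object of class `instrument_spec`.
#' @export
instrument_spec <- function(components = list(
                              list(type = "noise_band", band = c(40, 200)),
                              list(type = "transient_train", rate = 2),
                              list(type = "chord", fundamentals = c(110, 138.6, 164.8))),
                            duration = 1, seed = 1) {
  if (!length(components)) stop("instrument_spec: need at least one component")
  if (duration <= 0) stop("instrument_spec: duration must be > 0")
  structure(list(components = components, duration = duration,
                 seed = as.integer(seed)),
            class = "instrument_spec")
}

# reference RMS for all generated sources; a comfortable presentation level
# that keeps typical band envelopes inside the LGF operating range.
.synth_rms <- 0.05

#' Generate a voice-like track
#'
#' Deterministic per seed. RMS-normalized to the package reference level
#' (0.05 full scale).
#'
#' @param spec a [voice_spec()]. @param rate sampling rate (Hz).
#' @return an `audio_track` labelled `"voice"`.
#' @export
gen_voice_like <- function(spec, rate = 16000) {
  stopifnot(inherits(spec, "voice_spec"))
  n <- max(2L, round(spec$duration * rate))
  with_seed(spec$seed, {
    # slow random-walk F0 inside the range (reflecting at the edges)
    n_ctrl <- max(4L, ceiling(spec$duration * 8) + 1L)
    steps <- stats::rnorm(n_ctrl, 0, diff(spec$f0_range) / 6)
    walk <- cumsum(c(stats::runif(1, spec$f0_range[1L], spec$f0_range[2L]), steps))
    walk <- reflect_into(walk, spec$f0_range[1L], spec$f0_range[2L])
    f0 <- stats::approx(seq(0, 1, length.out = n_ctrl + 1L),
                        walk, xout = seq(0, 1, length.out = n))$y
    if (spec$vibrato_depth > 0) {
      vib_phase <- stats::runif(1, 0, 2 * pi)
      f0 <- f0 * 2^(spec$vibrato_depth / 1200 *
                      sin(2 * pi * spec$vibrato_rate * seq_len(n) / rate + vib_phase))
    }
    phase <- 2 * pi * cumsum(f0) / rate
    n_harm <- max(1L, floor((rate / 2 - 1) / spec$f0_range[2L]))
    n_harm <- min(n_harm, 30L)
    amps <- 10^(-spec$harmonic_rolloff * log2(seq_len(n_harm)) / 20)
    hph <- stats::runif(n_harm, 0, 2 * pi)
    s <- numeric(n)
    for (k in seq_len(n_harm)) s <- s + amps[k] * sin(k * phase + hph[k])
    # syllabic AM: raised cosine, never fully silent
    am_phase <- stats::runif(1, 0, 2 * pi)
    am <- 0.55 + 0.45 * cos(2 * pi * spec$syllable_rate * seq_len(n) / rate + am_phase)
    s <- s * am
    audio_track(s / sqrt(mean(s^2)) * .synth_rms, rate, "voice")
  })
}

reflect_into <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}

#' Generate an instrument-like track
#'
#' Sum of the requested components, each RMS-normalized before summation,
#' the total normalized to the package reference level. Deterministic per
#' seed. Transient trains place one onset every `1/rate` seconds starting
#' at t = 0.
#'
#' @param spec an [instrument_spec()]. @param rate sampling rate (Hz).
#' @return an `audio_track` labelled `"instruments"`.
#' @export
gen_instrument_like <- function(spec, rate = 16000) {
  stopifnot(inherits(spec, "instrument_spec"))
  n <- max(2L, round(spec$duration * rate))
  with_seed(spec$seed, {
    s <- numeric(n)
    for (comp in spec$components) {
      x <- switch(comp$type,
        noise_band = {
          w <- stats::rnorm(n)
          ny <- rate / 2
          lo <- comp$band[1L] / ny; hi <- min(comp$band[2L] / ny, 0.99)
          bf <- signal::butter(4, c(lo, hi), type = "pass")
          as.numeric(signal::filtfilt(bf, w))
        },
        transient_train = {
          onsets <- seq(0, spec$duration - 1e-9, by = 1 / comp$rate)
          x <- numeric(n)
          idx <- pmin(n, floor(onsets * rate) + 1L)
          # decaying noise burst at each onset
          burst_len <- min(n, round(0.02 * rate))
          burst_env <- exp(-seq_len(burst_len) / (0.004 * rate))
          for (i0 in idx) {
            j <- i0:min(n, i0 + burst_len - 1L)
            x[j] <- x[j] + burst_env[seq_along(j)] * stats::rnorm(length(j))
          }
          x
        },
        chord = {
          x <- numeric(n)
          tt <- seq_len(n) / rate
          for (f in comp$fundamentals)
            for (k in 1:4)
              x <- x + sin(2 * pi * f * k * tt + stats::runif(1, 0, 2 * pi)) / k
          x
        },
        stop("gen_instrument_like: unknown component type ", comp$type))
      s <- s + x / sqrt(mean(x^2))
    }
    audio_track(s / sqrt(mean(s^2)) * .synth_rms, rate, "instruments")
  })
}

#' Generate a paired-source mixture dataset
#'
#' Builds `n_items` two-source items mixed at `ratio_db` via
#' [mix_at_ratio()]. For `task = "speech"` the target is a female-range
#' voice surrogate (F0 165-255 Hz) and the interferer a male-range one
#' (85-155 Hz), the disjoint-F0 structure of concurrent-talker material.
#' For `task = "music"` the target is a voice surrogate over an
#' instrument-like bed (low noise band + transient train + chord). The
#' mixture is the exact sample-wise sum of the stored (post-scaling)
#' sources. Per-item seeds derive deterministically from `seed`, so the
#' same master seed reproduces the dataset byte for byte.
#'
#' @param n_items number of items (>= 1).
#' @param task `"speech"` or `"music"`.
#' @param ratio_db target-to-interferer energy ratio in dB (SIR for
#'   speech, VIR for music).
#' @param seed master seed.
#' @param duration item duration in seconds (default 1).
#' @param rate sampling rate (Hz).
#' @return list of items, each `list(mixture, sources, meta)`; the
#'   manifest data frame of all item metadata is attached as attribute
#'   `"manifest"`.
#' @export
make_mixture_dataset <- function(n_items, task = c("speech", "music"),
                                 ratio_db = 0, seed = 1, duration = 1,
                                 rate = 16000) {
  task <- match.arg(task)
  if (n_items < 1L) stop("make_mixture_dataset: n_items must be >= 1")
  items <- vector("list", n_items)
  man <- vector("list", n_items)
  for (i in seq_len(n_items)) {
    s1 <- (seed * 10000L + 2L * i) %% 2147483647L
    s2 <- (seed * 10000L + 2L * i + 1L) %% 2147483647L
    if (task == "speech") {
      target <- gen_voice_like(voice_spec(f0_range = c(165, 255),
                                          duration = duration, seed = s1), rate)
      target$label <- "target"
      interf <- gen_voice_like(voice_spec(f0_range = c(85, 155),
                                          duration = duration, seed = s2), rate)
      interf$label <- "interferer"
    } else {
      target <- gen_voice_like(voice_spec(f0_range = c(165, 255),
                                          duration = duration, seed = s1), rate)
      target$label <- "vocals"
      interf <- gen_instrument_like(instrument_spec(duration = duration, seed = s2), rate)
      interf$label <- "instruments"
    }
    mix <- mix_at_ratio(target, interf, ratio_db)
    comps <- attr(mix, "components")
    attr(mix, "components") <- NULL
    items[[i]] <- list(mixture = mix,
                       sources = list(comps$target, comps$interferer),
                       meta = list(item = i, task = task, ratio_db = ratio_db,
                                   seed_target = s1, seed_interferer = s2,
                                   duration = duration, rate = rate))
    man[[i]] <- as.data.frame(items[[i]]$meta)
  }
  attr(items, "manifest") <- do.call(rbind, man)
  items
}

#' Two-tone toy dataset for separation smoke experiments
#'
#' The smallest well-posed separation problem: each item mixes one
#' low-frequency and one high-frequency sinusoid (random frequency and
#' phase per item, disjoint bands) at 0 dB. Useful for verifying that a
#' separator architecture and its training loop learn at all, at toy cost;
#' not a stand-in for the voice/instrument material of
#' [make_mixture_dataset()].
#'
#' @param n_items number of items.
#' @param seed master seed (per-item seeds derive from it).
#' @param duration item duration in seconds.
#' @param low_band,high_band frequency ranges (Hz) for the two tones.
#' @param rate sampling rate (Hz).
#' @return list of items shaped like [make_mixture_dataset()] output.
#' @export
make_tone_dataset <- function(n_items, seed = 1, duration = 0.2,
                              low_band = c(250, 450), high_band = c(1200, 2000),
                              rate = 16000) {
  items <- vector("list", n_items)
  for (i in seq_len(n_items)) {
    s <- (seed * 1000L + i) %% 2147483647L
    items[[i]] <- with_seed(s, {
      f1 <- stats::runif(1, low_band[1L], low_band[2L])
      f2 <- stats::runif(1, high_band[1L], high_band[2L])
      tt <- seq_len(max(2L, round(duration * rate))) / rate
      a <- audio_track(.synth_rms * sqrt(2) * sin(2 * pi * f1 * tt + stats::runif(1, 0, 2 * pi)),
                       rate, "target")
      b <- audio_track(.synth_rms * sqrt(2) * sin(2 * pi * f2 * tt + stats::runif(1, 0, 2 * pi)),
                       rate, "interferer")
      mix <- mix_at_ratio(a, b, 0)
      comps <- attr(mix, "components")
      attr(mix, "components") <- NULL
      list(mixture = mix, sources = list(comps$target, comps$interferer),
           meta = list(item = i, f_low = f1, f_high = f2, seed = s))
    })
  }
  items
}

# ---- STFT helpers and the ideal-mask reference separator ------------------

stft_mat <- function(x, nfft = 256L, hop = 64L) {
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nfft) / nfft)
  n <- length(x)
  x <- c(x, numeric(nfft))
  starts <- seq.int(1L, n, by = hop)
  out <- vapply(starts, function(t0)
    stats::fft(x[t0:(t0 + nfft - 1L)] * w), complex(nfft))
  out
}

istft_mat <- function(S, hop = 64L, n_out) {
  nfft <- nrow(S)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nfft) / nfft)
  y <- numeric((ncol(S) - 1L) * hop + nfft)
  wsum <- numeric(length(y))
  for (j in seq_len(ncol(S))) {
    i0 <- (j - 1L) * hop
    seg <- Re(stats::fft(S[, j], inverse = TRUE)) / nfft
    y[i0 + seq_len(nfft)] <- y[i0 + seq_len(nfft)] + seg * w
    wsum[i0 + seq_len(nfft)] <- wsum[i0 + seq_len(nfft)] + w^2
  }
  y <- y / pmax(wsum, 1e-8)
  y[seq_len(n_out)]
}

#' Ideal-mask reference separation
#'
#' Oracle short-time binary mask computed from the true sources, applied
#' to the mixture and resynthesized. Not a learned method: it upper-bounds
#' what short-time spectral masking can do and certifies that a dataset's
#' sources are spectrally separable (well-posedness of the learning
#' tasks).
#'
#' @param mixture an `audio_track`.
#' @param sources list of true source `audio_track`s.
#' @param nfft,hop STFT geometry.
#' @return list of separated `audio_track`s, one per source.
#' @export
ideal_mask_separate <- function(mixture, sources, nfft = 256L, hop = 64L) {
  assert_track(mixture)
  # zero-pad so every real sample has full analysis-window coverage; the
  # weighted overlap-add inverse is ill-conditioned at bare signal edges
  # once frames are modified by a mask
  n <- length(mixture$samples)
  pad <- function(s) c(numeric(nfft), s, numeric(nfft))
  S_mix <- stft_mat(pad(mixture$samples), nfft, hop)
  mags <- lapply(sources, function(s) abs(stft_mat(pad(s$samples), nfft, hop)))
  best <- Reduce(function(a, b) pmax(a, b), mags)
  lapply(seq_along(sources), function(c_) {
    mask <- mags[[c_]] >= best
    y <- istft_mat(S_mix * mask, hop, n + 2L * nfft)
    audio_track(y[nfft + seq_len(n)], mixture$rate, sprintf("ideal_sep_%d", c_))
  })
}
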