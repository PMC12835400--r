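#' Loudness growth function parameters
#'
#' The LGF maps acoustic band envelopes onto normalized stimulation
#' magnitudes in `[0, 1]` with the logarithmic form used by Cochlear
#' devices: `y = log(1 + rho * u) / log(1 + rho)` with
#' `u = (x - base_level) / (sat_level - base_level)` clipped to `[0, 1]`.
#' Envelopes at or below `base_level` produce no stimulation (inactive);
#' envelopes at or above `sat_level` saturate at 1.
#'
#' @param rho compression steepness (dimensionless, > 0). Default 416.2,
#'   the steepness used in clinical ACE maps.
#' @param base_level envelope value mapped to zero output. Defaults assume
#'   band envelopes normalized so a full-scale bin-centred sinusoid has
#'   envelope ~1 (see [ace_config()]).
#' @param sat_level envelope value mapped to 1; must exceed `base_level`.
#' @return an object of class `lgf_params`.
#' @export
lgf_params <- function(rho = 416.2, base_level = 4 / 256, sat_level = 150 / 256) {
  if (!is.finite(rho) || rho <= 0) stop("lgf_params: rho must be > 0")
  if (!is.finite(base_level) || !is.finite(sat_level) ||
      base_level < 0 || base_level >= sat_level)
    stop("lgf_params: need 0 <= base_level < sat_level")
  structure(list(rho = rho, base_level = base_level, sat_level = sat_level),
            class = "lgf_params")
}

#' AGC (front-end compressor) parameters
#'
#' A static compression curve with peak-follower smoothing. Disabled by
#' default: the chain is then exactly linear up to the filterbank.
#'
#' @param enabled logical; identity when `FALSE`.
#' @param threshold_db compression threshold in dB re full scale.
#' @param ratio compression ratio (`Inf` = limiter).
#' @param attack_ms,release_ms peak-follower time constants (ms).
#' @return an object of class `agc_params`.
#' @export
agc_params <- function(enabled = FALSE, threshold_db = -20, ratio = Inf,
                       attack_ms = 5, release_ms = 75) {
  if (!is.finite(threshold_db)) stop("agc_params: threshold_db must be finite")
  if (!(ratio >= 1)) stop("agc_params: ratio must be >= 1 (Inf for limiting)")
  structure(list(enabled = isTRUE(enabled), threshold_db = threshold_db,
                 ratio = ratio, attack_ms = attack_ms, release_ms = release_ms),
            class = "agc_params")
}

#' Subject fitting map
#'
#' Per-electrode threshold (THL) and most-comfortable (MCL) stimulation
#' levels in clinical current units, bounding each electrode's electrical
#' dynamic range, plus the global channel counts.
#'
#' @param M electrode count (default 22).
#' @param N maxima retained per frame (default 8).
#' @param thl,mcl numeric vectors of length `M` (recycled if scalar);
#'   `thl[m] < mcl[m]` required.
#' @param stim_rate per-channel stimulation rate in Hz.
#' @return an object of class `subject_map`.
#' @export
subject_map <- function(M = 22, N = 8, thl = 100, mcl = 200, stim_rate = 900) {
  M <- as.integer(M); N <- as.integer(N)
  if (N < 1L || N > M) stop("subject_map: need 1 <= N <= M")
  thl <- rep_len(as.numeric(thl), M)
  mcl <- rep_len(as.numeric(mcl), M)
  if (any(!is.finite(thl)) || any(!is.finite(mcl)) || any(thl >= mcl))
    stop("subject_map: need finite thl[m] < mcl[m] for all electrodes")
  if (!is.finite(stim_rate) || stim_rate <= 0) stop("subject_map: stim_rate must be > 0")
  structure(list(M = M, N = N, thl = thl, mcl = mcl, stim_rate = stim_rate),
            class = "subject_map")
}

#' Default FFT bin to band grouping
#'
#' Groups the usable FFT bins into `M` contiguous analysis bands with
#' approximately logarithmic spacing, each band at least one bin wide and
#' widths non-decreasing towards high frequencies, in the style of the
#' 22-band clinical filterbank tables. Bin 1 is DC; the grouping starts at
#' `f_lo` and ends at the Nyquist bin.
#'
#' @param fft_size FFT length in samples.
#' @param fs sampling rate (Hz).
#' @param M number of bands.
#' @param f_lo lower edge of the first band (Hz).
#' @return integer vector of length `n_bins_used` mapping each used bin
#'   (attribute `bins`: the FFT bin indices, 1-based with DC = 1) to a band
#'   in `1..M`.
#' @export
default_band_table <- function(fft_size = 128, fs = 16000, M = 22, f_lo = 187.5) {
  binw <- fs / fft_size
  first_bin <- max(2L, as.integer(round(f_lo / binw)) + 1L)  # 1-based, DC = 1
  last_bin <- fft_size %/% 2L + 1L                            # Nyquist bin
  n_bins <- last_bin - first_bin + 1L
  if (n_bins < M) stop("default_band_table: fewer usable bins than bands")
  f1 <- (first_bin - 1L) * binw
  f2 <- (last_bin - 1L) * binw
  edges <- exp(seq(log(f1), log(f2), length.out = M + 1L))
  cuts <- as.integer(round(edges / binw)) + 1L
  cuts[1L] <- first_bin; cuts[M + 1L] <- last_bin + 1L
  # enforce strictly increasing cut points (>= 1 bin per band)
  for (i in 2L:(M + 1L)) if (cuts[i] <= cuts[i - 1L]) cuts[i] <- cuts[i - 1L] + 1L
  if (cuts[M + 1L] > last_bin + 1L) {
    # ran over the top: push surplus back down while keeping monotonicity
    for (i in (M + 1L):2L) {
      cuts[i] <- min(cuts[i], last_bin + 1L - ((M + 1L) - i))
      if (cuts[i] <= cuts[i - 1L]) cuts[i - 1L] <- cuts[i] - 1L
    }
    cuts[1L] <- first_bin
  }
  band <- rep.int(seq_len(M), times = diff(cuts))
  structure(band, bins = seq.int(first_bin, last_bin))
}

#' Full ACE strategy configuration
#'
#' Bundles the filterbank geometry, LGF, AGC, channel counts and stage
#' bypass switches for [encode_ace()]. Defaults: 16 kHz input, 128-point
#' FFT with a Hann window, 22 bands, 8 maxima, 900 Hz channel stimulation
#' rate (`hop = round(fs / stim_rate)` samples), LGF per [lgf_params()],
#' AGC disabled. FFT magnitudes are normalized by `sum(window) / 2` so that
#' a full-scale sinusoid at a bin centre has envelope ~1, putting ordinary
#' material inside the LGF's operating range.
#'
#' Stage switches: `bypass_lgf` replaces the LGF by the identity (raw
#' envelopes pass through), `bypass_nofm` retains all bands; with AGC also
#' disabled the chain is linear in the input amplitude, which is the
#' configuration used by the linear-limit equivalence checks.
#'
#' @param fs sampling rate (Hz).
#' @param fft_size FFT length (samples).
#' @param hop analysis hop (samples); default `round(fs / stim_rate)`.
#' @param window `"hann"` or `"rect"`.
#' @param M,N channel counts (N maxima of M bands).
#' @param stim_rate channel stimulation rate (Hz), sets the default hop.
#' @param band_table bin-to-band map, e.g. from [default_band_table()].
#' @param lgf an [lgf_params()] object.
#' @param agc an [agc_params()] object.
#' @param map optional [subject_map()]; when supplied and
#'   `output = "current"`, LGF magnitudes are mapped into `[thl, mcl]`.
#' @param output `"lgf"` (normalized magnitudes) or `"current"`.
#' @param bypass_lgf,bypass_nofm stage bypass switches.
#' @return an object of class `ace_config`.
#' @export
ace_config <- function(fs = 16000, fft_size = 128, hop = NULL, window = "hann",
                       M = 22, N = 8, stim_rate = 900,
                       band_table = NULL, lgf = lgf_params(), agc = agc_params(),
                       map = NULL, output = c("lgf", "current"),
                       bypass_lgf = FALSE, bypass_nofm = FALSE) {
  output <- match.arg(output)
  M <- as.integer(M); N <- as.integer(N)
  if (N < 1L || N > M) stop("ace_config: need 1 <= N <= M")
  if (is.null(hop)) hop <- as.integer(round(fs / stim_rate))
  hop <- as.integer(hop)
  if (hop < 1L || hop > fft_size) stop("ace_config: need 0 < hop <= fft_size")
  if (is.null(band_table)) band_table <- default_band_table(fft_size, fs, M)
  bins <- attr(band_table, "bins")
  if (is.null(bins) || length(bins) != length(band_table))
    stop("ace_config: band_table needs a 'bins' attribute of equal length")
  if (!all(sort(unique(as.integer(band_table))) == seq_len(M)))
    stop("ace_config: band_table must cover bands 1..M")
  if (is.unsorted(band_table)) stop("ace_config: band_table must be monotone")
  if (anyDuplicated(bins)) stop("ace_config: each bin may appear once")
  if (output == "current" && is.null(map)) map <- subject_map(M = M, N = N)
  if (!is.null(map) && map$M != M) stop("ace_config: map$M != M")
  w <- switch(window,
              hann = 0.5 - 0.5 * cos(2 * pi * seq_len(fft_size) / fft_size),
              rect = rep(1, fft_size),
              stop("ace_config: unknown window ", window))
  structure(list(fs = fs, fft_size = as.integer(fft_size), hop = hop,
                 window = window, win = w, fft_scale = 2 / sum(w),
                 M = M, N = N, stim_rate = stim_rate,
                 band_table = band_table, lgf = lgf, agc = agc, map = map,
                 output = output, bypass_lgf = isTRUE(bypass_lgf),
                 bypass_nofm = isTRUE(bypass_nofm)),
            class = "ace_config")
}

#' Apply adaptive gain control
#'
#' Static compression above threshold with an attack/release peak follower.
#' Identity when the AGC is disabled. With `ratio = Inf` the curve is a
#' limiter: steady-state peaks are held at the threshold.
#'
#' @param x an `audio_track` with finite samples.
#' @param agc an [agc_params()] object.
#' @return gain-controlled `audio_track` of the same length and rate.
#' @export
apply_agc <- function(x, agc = agc_params()) {
  assert_track(x)
  if (!inherits(agc, "agc_params")) stop("apply_agc: agc must be agc_params")
  if (!agc$enabled) return(x)
  s <- x$samples
  thr <- 10^(agc$threshold_db / 20)
  # instant-attack peak follower with exponential release
  c_rel <- exp(-1 / (agc$release_ms * 1e-3 * x$rate))
  lev <- numeric(length(s))
  l <- 0
  for (n in seq_along(s)) {
    l <- max(abs(s[n]), l * c_rel)
    lev[n] <- l
  }
  gain <- rep(1, length(s))
  over <- lev > thr
  if (any(over)) {
    if (is.infinite(agc$ratio)) {
      gain[over] <- thr / lev[over]
    } else {
      # output level thr * (lev/thr)^(1/ratio)  =>  gain = (lev/thr)^(1/ratio - 1)
      gain[over] <- (lev[over] / thr)^(1 / agc$ratio - 1)
    }
  }
  # smooth downward gain moves with the attack time constant (zipper control)
  if (agc$attack_ms > 0) {
    c_att <- exp(-1 / (agc$attack_ms * 1e-3 * x$rate))
    g <- 1
    for (n in seq_along(gain)) {
      g <- if (gain[n] < g) c_att * g + (1 - c_att) * gain[n] else gain[n]
      gain[n] <- g
    }
  }
  audio_track(s * gain, x$rate, x$label)
}

#' FFT analysis filterbank
#'
#' Frames the signal with the configured window and hop and returns the
#' one-sided complex spectra, scaled so a full-scale bin-centred sinusoid
#' has magnitude ~1 in its bin. Frames are complete windows only.
#'
#' @param x an `audio_track` at the configured rate.
#' @param cfg an [ace_config()].
#' @return complex matrix of dimension `n_frames x (fft_size/2 + 1)`.
#' @export
analysis_filterbank <- function(x, cfg) {
  assert_track(x)
  stopifnot(inherits(cfg, "ace_config"))
  s <- x$samples
  K <- cfg$fft_size
  if (length(s) < K) stop("analysis_filterbank: signal shorter than one window")
  starts <- seq.int(1L, length(s) - K + 1L, by = cfg$hop)
  n_bins <- K %/% 2L + 1L
  frames <- vapply(starts, function(t0) {
    sp <- stats::fft(s[t0:(t0 + K - 1L)] * cfg$win)
    sp[seq_len(n_bins)]
  }, complex(n_bins))
  t(frames) * cfg$fft_scale
}

#' Band envelopes from filterbank frames
#'
#' The envelope of each analysis band is the root-sum-square of the
#' magnitudes of its FFT bins (energy-preserving combination; a band with a
#' single bin reduces to that bin's magnitude).
#'
#' @param frames complex frame matrix from [analysis_filterbank()].
#' @param cfg an [ace_config()].
#' @return nonnegative envelope matrix, `n_frames x M`.
#' @export
band_envelopes <- function(frames, cfg) {
  stopifnot(inherits(cfg, "ace_config"))
  bins <- attr(cfg$band_table, "bins")
  if (max(bins) > ncol(frames))
    stop("band_envelopes: band table refers to bins beyond the frame width")
  p <- abs(frames[, bins, drop = FALSE])^2
  env <- vapply(seq_len(cfg$M), function(m)
    sqrt(rowSums(p[, cfg$band_table == m, drop = FALSE])), numeric(nrow(frames)))
  matrix(env, nrow = nrow(frames), ncol = cfg$M)
}

#' Loudness growth function compression
#'
#' Applies the logarithmic LGF elementwise. Entries at or below
#' `base_level` are inactive (`NA`); entries at or above `sat_level` map
#' to 1. Monotone non-decreasing in its input.
#'
#' @param env nonnegative envelope matrix (`T x M`).
#' @param p an [lgf_params()] object.
#' @return matrix of magnitudes in `[0, 1]` with `NA` marking inactive.
#' @export
lgf_compress <- function(env, p = lgf_params()) {
  if (!inherits(p, "lgf_params")) stop("lgf_compress: p must be lgf_params")
  if (any(env < 0, na.rm = TRUE)) stop("lgf_compress: envelopes must be nonnegative")
  u <- (env - p$base_level) / (p$sat_level - p$base_level)
  y <- log1p(p$rho * pmin(pmax(u, 0), 1)) / log1p(p$rho)
  y[u <= 0] <- NA_real_
  y
}

#' N-of-M maxima selection
#'
#' Retains, per frame, the `N` largest positive magnitudes and marks all
#' other channels inactive (`NA`). Ties are broken toward the lower channel
#' index. Zero or `NA` entries never become active; frames with fewer than
#' `N` positive entries keep all of them.
#'
#' @param mag magnitude matrix (`T x M`), `NA` = inactive.
#' @param N number of maxima to retain.
#' @return sparse magnitude matrix of the same shape.
#' @export
select_n_of_m <- function(mag, N) {
  N <- as.integer(N)
  if (N < 1L || N > ncol(mag)) stop("select_n_of_m: need 1 <= N <= M")
  out <- matrix(NA_real_, nrow(mag), ncol(mag))
  for (t in seq_len(nrow(mag))) {
    v <- mag[t, ]
    cand <- which(!is.na(v) & v > 0)
    if (!length(cand)) next
    ord <- cand[order(-v[cand], cand)]
    keep <- ord[seq_len(min(N, length(ord)))]
    out[t, keep] <- v[keep]
  }
  out
}

#' Map LGF magnitudes to clinical current units
#'
#' Affine map of active entries from `[0, 1]` onto each electrode's
#' electrical dynamic range `[thl[m], mcl[m]]`. Inactive entries stay
#' inactive, so no sub-threshold stimulation is ever emitted.
#'
#' @param sparse magnitude matrix (`T x M`) in `[0, 1]` with `NA` inactive.
#' @param map a [subject_map()].
#' @return current-domain matrix of the same shape.
#' @export
map_to_current <- function(sparse, map) {
  stopifnot(inherits(map, "subject_map"))
  if (ncol(sparse) != map$M) stop("map_to_current: column count != map$M")
  rng <- any(sparse < 0 | sparse > 1, na.rm = TRUE)
  if (rng) stop("map_to_current: inputs must lie in [0, 1]")
  t(apply(sparse, 1L, function(v) map$thl + (map$mcl - map$thl) * v))
}

#' Construct an electrodogram object
#'
#' A time-frame by electrode matrix of stimulation magnitudes. Inactive
#' entries are `NA`. `domain_tag` records whether values are normalized LGF
#' magnitudes (`"lgf"`, in `[0, 1]`) or mapped clinical current units
#' (`"current"`).
#'
#' @param values `T x M` numeric matrix, `NA` = inactive.
#' @param frame_rate frames per second.
#' @param domain_tag `"lgf"` or `"current"`.
#' @param N maxima bound per frame (metadata).
#' @return an object of class `electrodogram`.
#' @export
electrodogram <- function(values, frame_rate, domain_tag = c("lgf", "current"), N = NA_integer_) {
  domain_tag <- match.arg(domain_tag)
  values <- as.matrix(values)
  structure(list(values = values, frame_rate = frame_rate,
                 domain_tag = domain_tag, M = ncol(values), N = as.integer(N)),
            class = "electrodogram")
}

#' @export
print.electrodogram <- function(x, ...) {
  act <- mean(rowSums(!is.na(x$values)))
  cat(sprintf("<electrodogram> %d frames x %d channels @ %.1f frames/s [%s], mean active/frame %.2f\n",
              nrow(x$values), x$M, x$frame_rate, x$domain_tag, act))
  invisible(x)
}

#' @export
dim.electrodogram <- function(x) dim(x$values)

#' Encode audio with the ACE strategy
#'
#' Runs the full deterministic chain AGC -> FFT filterbank -> band
#' envelopes -> LGF -> N-of-M -> (optional) subject mapping and returns the
#' electrodogram. Stage bypasses in the config are honoured; with AGC
#' disabled and LGF and N-of-M bypassed the chain is linear in the input.
#'
#' @param x an `audio_track`; resampled (with a warning) if its rate
#'   differs from `cfg$fs`.
#' @param cfg an [ace_config()].
#' @return an `electrodogram`.
#' @export
encode_ace <- function(x, cfg = ace_config()) {
  assert_track(x)
  stopifnot(inherits(cfg, "ace_config"))
  if (x$rate != cfg$fs) {
    warning(sprintf("encode_ace: resampling input from %g to %g Hz", x$rate, cfg$fs))
    x <- track_resample(x, cfg$fs)
  }
  x <- apply_agc(x, cfg$agc)
  frames <- analysis_filterbank(x, cfg)
  env <- band_envelopes(frames, cfg)
  if (cfg$bypass_lgf) {
    mag <- env
    mag[mag == 0] <- NA_real_
  } else {
    mag <- lgf_compress(env, cfg$lgf)
  }
  if (!cfg$bypass_nofm) mag <- select_n_of_m(mag, cfg$N)
  if (cfg$output == "current") {
    if (cfg$bypass_lgf) stop("encode_ace: current output requires the LGF stage")
    mag <- map_to_current(mag, cfg$map)
  }
  electrodogram(mag, frame_rate = cfg$fs / cfg$hop, domain_tag = cfg$output,
                N = if (cfg$bypass_nofm) cfg$M else cfg$N)
}

# ---- electrodogram text I/O ----------------------------------------------

#' Write an electrodogram to a delimited text file
#'
#' Tab-separated `frames x channels` matrix preceded by commented header
#' lines recording frame rate, domain, channel counts and the inactive
#' sentinel (`NA`).
#'
#' @param e an `electrodogram`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_electrodogram <- function(e, path) {
  stopifnot(inherits(e, "electrodogram"))
  hdr <- c(sprintf("# frame_rate: %.10g", e$frame_rate),
           sprintf("# domain_tag: %s", e$domain_tag),
           sprintf("# M: %d", e$M),
           sprintf("# N: %d", e$N),
           "# inactive: NA")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(e$values, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, na = "NA")
  invisible(path)
}

#' Read an electrodogram written by [write_electrodogram()]
#' @param path input path.
#' @return an `electrodogram`.
#' @export
read_electrodogram <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(ln)) stop("read_electrodogram: missing header field ", key)
    trimws(sub(paste0("^# ", key, ":"), "", ln[1L]))
  }
  vals <- utils::read.table(text = lines[!grepl("^#", lines)], sep = "\t",
                            na.strings = "NA")
  vals <- unname(as.matrix(vals))
  electrodogram(vals,
                frame_rate = as.numeric(get_field("frame_rate")),
                domain_tag = get_field("domain_tag"),
                N = suppressWarnings(as.integer(get_field("N"))))
}
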