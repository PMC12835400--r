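#' Construct an audio track
#'
#' An `audio_track` is the basic time-domain container of the package: a
#' mono, real-valued sample sequence with its sampling rate and a free-text
#' role label ("target", "interferer", "vocals", "instruments", "mixture", ...).
#' Samples are dimensionless amplitudes, nominally in `[-1, 1]`.
#'
#' @param samples numeric vector of samples; must be finite and non-empty.
#' @param rate sampling rate in samples/second (default 16000).
#' @param label free-text role tag.
#' @return an object of class `audio_track`.
#' @export
audio_track <- function(samples, rate = 16000, label = "") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("audio_track: need at least one sample")
  if (!all(is.finite(samples))) stop("audio_track: samples must be finite")
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("audio_track: rate must be a positive scalar")
  structure(list(samples = samples, rate = rate, label = as.character(label)[1L]),
            class = "audio_track")
}

#' @export
print.audio_track <- function(x, ...) {
  dur <- length(x$samples) / x$rate
  cat(sprintf("<audio_track> %s: %d samples @ %g Hz (%.3f s), rms %.4g\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$samples), x$rate, dur, track_rms(x)))
  invisible(x)
}

#' @export
length.audio_track <- function(x) length(x$samples)

is_audio_track <- function(x) inherits(x, "audio_track")

assert_track <- function(x, what = "input") {
  if (!is_audio_track(x)) stop(sprintf("%s must be an audio_track", what))
  invisible(x)
}

#' Root-mean-square level of a track
#' @param x an `audio_track`.
#' @return scalar RMS amplitude.
#' @export
track_rms <- function(x) {
  assert_track(x)
  sqrt(mean(x$samples^2))
}

#' Scale a track by an amplitude factor
#' @param x an `audio_track`.
#' @param factor linear amplitude factor.
#' @return scaled `audio_track` (label preserved).
#' @export
track_scale <- function(x, factor) {
  assert_track(x)
  audio_track(x$samples * factor, x$rate, x$label)
}

#' Sum two equally long tracks sample-wise
#' @param a,b `audio_track`s with equal length and rate.
#' @param label label for the result.
#' @return `audio_track`.
#' @export
track_sum <- function(a, b, label = "mixture") {
  assert_track(a, "a"); assert_track(b, "b")
  if (length(a$samples) != length(b$samples)) stop("track_sum: length mismatch")
  if (a$rate != b$rate) stop("track_sum: rate mismatch")
  audio_track(a$samples + b$samples, a$rate, label)
}

#' Resample a track to a new rate
#'
#' Polyphase resampling via [signal::resample()]. Used when file input does
#' not match the 16 kHz processing rate; callers warn when this happens.
#'
#' @param x an `audio_track`.
#' @param rate target sampling rate (Hz).
#' @return resampled `audio_track`.
#' @export
track_resample <- function(x, rate) {
  assert_track(x)
  if (x$rate == rate) return(x)
  fr <- as.integer(round(rate))
  fx <- as.integer(round(x$rate))
  g <- gcd_int(fr, fx)
  y <- signal::resample(x$samples, p = fr %/% g, q = fx %/% g)
  audio_track(as.numeric(y), rate, x$label)
}

gcd_int <- function(a, b) {
  while (b != 0L) { t <- b; b <- a %% b; a <- t }
  a
}

# ---- WAV I/O --------------------------------------------------------------
# Minimal RIFF/WAVE reader and writer for mono (or first-channel) audio.
# Supports PCM 16/24/32-bit (format 1) and IEEE float32 (format 3).

#' Read a WAV file
#'
#' Reads mono audio (the first channel of multichannel files, with a warning)
#' and rescales integer PCM to `[-1, 1]`. If `target_rate` is given and
#' differs from the file rate, the track is resampled with a warning.
#'
#' @param path path to a `.wav` file.
#' @param label role label for the returned track.
#' @param target_rate optional rate to resample to (e.g. 16000).
#' @return an `audio_track`.
#' @export
read_wav <- function(path, label = "", target_rate = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("read_wav: not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1L, 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("read_wav: not a WAVE file: ", path)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", sz)
      fmt <- list(
        format    = raw_u16(fmt_raw, 1L),
        channels  = raw_u16(fmt_raw, 3L),
        rate      = raw_u32(fmt_raw, 5L),
        bits      = raw_u16(fmt_raw, 15L))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2L == 1L) invisible(readBin(con, "raw", 1L))  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("read_wav: missing fmt/data chunk")
  bytes <- fmt$bits %/% 8L
  n_total <- length(data_raw) %/% bytes
  if (fmt$format == 1L && fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", n_total, 2L, signed = TRUE,
                 endian = "little") / 32768
  } else if (fmt$format == 1L && fmt$bits == 24L) {
    m <- matrix(as.integer(data_raw[seq_len(n_total * 3L)]), nrow = 3L)
    v <- m[1L, ] + 256L * m[2L, ] + 65536L * m[3L, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    x <- v / 8388608
  } else if (fmt$format == 1L && fmt$bits == 32L) {
    x <- readBin(data_raw, "integer", n_total, 4L, endian = "little") / 2147483648
  } else if (fmt$format == 3L && fmt$bits == 32L) {
    x <- readBin(data_raw, "double", n_total, 4L, endian = "little")
  } else {
    stop(sprintf("read_wav: unsupported format %d / %d bits", fmt$format, fmt$bits))
  }
  if (fmt$channels > 1L) {
    warning(sprintf("read_wav: %d channels in %s; keeping channel 1", fmt$channels, path))
    x <- x[seq(1L, length(x), by = fmt$channels)]
  }
  tr <- audio_track(x, fmt$rate, label)
  if (!is.null(target_rate) && target_rate != fmt$rate) {
    warning(sprintf("read_wav: resampling %s from %d to %g Hz", path, fmt$rate, target_rate))
    tr <- track_resample(tr, target_rate)
  }
  tr
}

raw_u16 <- function(r, i) as.integer(r[i]) + 256L * as.integer(r[i + 1L])
raw_u32 <- function(r, i) {
  as.numeric(as.integer(r[i])) + 256 * as.integer(r[i + 1L]) +
    65536 * as.integer(r[i + 2L]) + 16777216 * as.integer(r[i + 3L])
}

#' Write a WAV file
#'
#' @param x an `audio_track`; samples outside `[-1, 1]` are clipped with a
#'   warning for integer formats.
#' @param path output path.
#' @param bits one of 16, 24 (PCM) or "float" (IEEE float32).
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, bits = 16) {
  assert_track(x)
  s <- x$samples
  float <- identical(bits, "float")
  if (!float) {
    bits <- as.integer(bits)
    if (!bits %in% c(16L, 24L)) stop("write_wav: bits must be 16, 24 or \"float\"")
    if (any(abs(s) > 1)) {
      warning("write_wav: clipping samples outside [-1, 1]")
      s <- pmax(-1, pmin(1, s))
    }
  }
  con <- file(path, "wb")
  on.exit(close(con))
  nbytes <- if (float) 4L else bits %/% 8L
  data_size <- length(s) * nbytes
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(if (float) 3L else 1L, con, 2L, endian = "little")  # format tag
  writeBin(1L, con, 2L, endian = "little")                     # channels
  writeBin(as.integer(round(x$rate)), con, 4L, endian = "little")
  writeBin(as.integer(round(x$rate) * nbytes), con, 4L, endian = "little")
  writeBin(as.integer(nbytes), con, 2L, endian = "little")     # block align
  writeBin(if (float) 32L else bits, con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4L, endian = "little")
  if (float) {
    writeBin(s, con, 4L, endian = "little")
  } else if (bits == 16L) {
    v <- pmax(-32768L, pmin(32767L, as.integer(round(s * 32768))))
    writeBin(v, con, 2L, endian = "little")
  } else {
    v <- pmax(-8388608L, pmin(8388607L, as.integer(round(s * 8388608))))
    v <- ifelse(v < 0L, v + 16777216L, v)
    b <- rbind(v %% 256L, (v %/% 256L) %% 256L, (v %/% 65536L) %% 256L)
    writeBin(as.raw(b), con)
  }
  invisible(path)
}

# Local, restorable RNG scope: every stochastic operation in the package takes
# an explicit seed and runs under this helper so global RNG state is untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% 2147483647))
  }
  force(code)
}
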